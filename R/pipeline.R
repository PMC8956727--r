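# End-to-end orchestration: extract -> compose -> stylize under a single
# configuration object. The configuration exposes exactly 13 user-tunable
# stage parameters (the knobs that take non-default values in practice),
# grouped by pipeline stage:
#   colonies clustering        1  (overlap threshold)
#   unsharp mask filtering     2  (radius, amount)
#   CIELab thresholding        2  (L*, b* thresholds)
#   artifact-mask dilation     1  (radius)
#   speckle noise cancellation 2  (NLM strength, patch)
#   Chan-Vese segmentation     2  (mu, max iterations)
#   segmentation-mask dilation 1  (radius)
#   blending mask              1  (gamma)
#   neural style transfer      1  (lambda)
# Everything else (patch size, seeds, counts, architecture) is structural.

stage_param_counts <- function() {
  c(clustering = 1L, unsharp = 2L, cielab_threshold = 2L,
    artifact_dilation = 1L, speckle = 2L, chan_vese = 2L,
    segmentation_dilation = 1L, blending = 1L, style_transfer = 1L)
}

#' Full pipeline configuration
#'
#' Bundles the 13 tunable stage parameters (see [config_inventory()]) with
#' the structural settings of a generation run.
#'
#' @param overlap_threshold colony-clustering overlap threshold.
#' @param unsharp_radius,unsharp_amount unsharp-mask stage.
#' @param dark_L_threshold,dark_b_threshold CIELab artifact thresholds.
#' @param dark_dilate_radius artifact-mask dilation radius.
#' @param nlm_strength,nlm_patch speckle-cancellation stage.
#' @param cv_mu,cv_max_iter Chan-Vese stage.
#' @param seg_dilate_radius segmentation-mask dilation radius.
#' @param blend_gamma blending-mask exponent.
#' @param lambda_weight style-transfer weight.
#' @param patch_size,count_mean,cutout_margin,max_place_attempts,clip_keep_fraction,allow_scaling
#'   structural composition settings (see [composition_config()]).
#' @param n_annotated_dishes,n_empty_dishes,n_styles input-set sizes used
#'   when dishes are generated as fixtures rather than read from disk.
#' @param style_iterations,style_learning_rate,style_arch,patches_per_tile
#'   structural stylization settings (see [style_config()]).
#' @param species_labels closed label set.
#' @param fixture a [fixture_config()] for self-generated inputs.
#' @param dishes_dir optional directory of PNG+JSON dish pairs (written by
#'   [write_fixture_set()] or following the same dialect); `NULL` means
#'   generate fixtures in memory.
#' @return list of class `gen_config`.
#' @export
gen_config <- function(overlap_threshold = 0.01,
                       unsharp_radius = 2, unsharp_amount = 1,
                       dark_L_threshold = 40, dark_b_threshold = -5,
                       dark_dilate_radius = 2,
                       nlm_strength = 8, nlm_patch = 3,
                       cv_mu = 0.25, cv_max_iter = 200L,
                       seg_dilate_radius = 2, blend_gamma = 1,
                       lambda_weight = 0.05,
                       patch_size = 512L, count_mean = 10,
                       cutout_margin = 4, max_place_attempts = 50L,
                       clip_keep_fraction = 0.3, allow_scaling = FALSE,
                       n_annotated_dishes = 10L, n_empty_dishes = 10L,
                       n_styles = 20L,
                       style_iterations = 200L, style_learning_rate = 1e-4,
                       style_arch = "highres", patches_per_tile = 4L,
                       species_labels = agar_species(),
                       fixture = fixture_config(),
                       dishes_dir = NULL) {
  structure(list(
    stages = list(
      clustering = list(overlap_threshold = overlap_threshold),
      unsharp = list(radius = unsharp_radius, amount = unsharp_amount),
      cielab_threshold = list(dark_L = dark_L_threshold,
                              dark_b = dark_b_threshold),
      artifact_dilation = list(radius = dark_dilate_radius),
      speckle = list(nlm_strength = nlm_strength, nlm_patch = nlm_patch),
      chan_vese = list(mu = cv_mu, max_iter = as.integer(cv_max_iter)),
      segmentation_dilation = list(radius = seg_dilate_radius),
      blending = list(gamma = blend_gamma),
      style_transfer = list(lambda = lambda_weight)),
    structural = list(
      patch_size = as.integer(patch_size), count_mean = count_mean,
      cutout_margin = cutout_margin,
      max_place_attempts = as.integer(max_place_attempts),
      clip_keep_fraction = clip_keep_fraction,
      allow_scaling = allow_scaling,
      n_annotated_dishes = as.integer(n_annotated_dishes),
      n_empty_dishes = as.integer(n_empty_dishes),
      n_styles = as.integer(n_styles),
      style_iterations = as.integer(style_iterations),
      style_learning_rate = style_learning_rate,
      style_arch = style_arch,
      patches_per_tile = as.integer(patches_per_tile),
      species_labels = species_labels),
    fixture = fixture,
    dishes_dir = dishes_dir), class = "gen_config")
}

#' Inventory of the tunable stage parameters
#'
#' @param cfg a [gen_config()].
#' @return data.frame with columns `stage`, `n_params`.
#' @export
config_inventory <- function(cfg) {
  data.frame(stage = names(cfg$stages),
             n_params = unname(lengths(cfg$stages)))
}

#' Validate a pipeline configuration
#'
#' Checks value ranges, the 13-parameter stage inventory and label-set
#' consistency. A style weight above 0.05 yields a warning finding (class
#' fidelity degrades with too much style), not an error.
#'
#' @param cfg a [gen_config()].
#' @return list with character vectors `errors` and `warnings` plus the
#'   `inventory` data.frame.
#' @export
validate_config <- function(cfg) {
  errors <- character(); warnings <- character()
  s <- cfg$stages
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(is.numeric(s$clustering$overlap_threshold) &&
        s$clustering$overlap_threshold >= 0 && s$clustering$overlap_threshold < 1,
      "clustering.overlap_threshold must be in [0, 1)")
  chk(s$unsharp$radius >= 0, "unsharp.radius must be >= 0")
  chk(is.numeric(s$unsharp$amount), "unsharp.amount must be numeric")
  chk(is.numeric(s$cielab_threshold$dark_L), "cielab_threshold.dark_L must be numeric")
  chk(is.numeric(s$cielab_threshold$dark_b), "cielab_threshold.dark_b must be numeric")
  chk(s$artifact_dilation$radius >= 0, "artifact_dilation.radius must be >= 0")
  chk(s$speckle$nlm_strength >= 0, "speckle.nlm_strength must be >= 0")
  chk(s$speckle$nlm_patch >= 1, "speckle.nlm_patch must be >= 1")
  chk(s$chan_vese$mu >= 0, "chan_vese.mu must be >= 0")
  chk(s$chan_vese$max_iter >= 1, "chan_vese.max_iter must be >= 1")
  chk(s$segmentation_dilation$radius >= 0, "segmentation_dilation.radius must be >= 0")
  chk(s$blending$gamma > 0, "blending.gamma must be > 0")
  chk(s$style_transfer$lambda >= 0 && s$style_transfer$lambda <= 1,
      "style_transfer.lambda must be in [0, 1]")
  chk(cfg$structural$count_mean > 0, "structural.count_mean must be > 0")
  chk(cfg$structural$patch_size > 0, "structural.patch_size must be > 0")
  labels <- cfg$structural$species_labels
  chk(length(labels) >= 1 && !anyDuplicated(labels),
      "structural.species_labels must be a nonempty set of unique labels")
  inv <- config_inventory(cfg)
  want <- stage_param_counts()
  if (!identical(setNames(inv$n_params, inv$stage), want)) {
    errors <- c(errors, "stage parameter inventory does not match the expected 13-parameter layout")
  }
  if (isTRUE(s$style_transfer$lambda > 0.05)) {
    warnings <- c(warnings, sprintf(
      "style_transfer.lambda = %g > 0.05: strong stylization degrades species appearance fidelity",
      s$style_transfer$lambda))
  }
  list(errors = errors, warnings = warnings, inventory = inv)
}

#' Write / read a configuration as YAML
#'
#' Flat stage-grouped key-value document; unknown keys are rejected by
#' reconstruction through [gen_config()].
#'
#' @param cfg a [gen_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `gen_config` (read).
#' @export
write_gen_config <- function(cfg, path) {
  yaml::write_yaml(list(stages = cfg$stages, structural = cfg$structural,
                        fixture = unclass(cfg$fixture),
                        dishes_dir = cfg$dishes_dir), path)
  invisible(path)
}

#' @rdname write_gen_config
#' @export
read_gen_config <- function(path) {
  doc <- yaml::read_yaml(path)
  s <- doc$stages; st <- doc$structural
  fx <- if (!is.null(doc$fixture)) do.call(fixture_config, doc$fixture) else fixture_config()
  gen_config(
    overlap_threshold = s$clustering$overlap_threshold,
    unsharp_radius = s$unsharp$radius, unsharp_amount = s$unsharp$amount,
    dark_L_threshold = s$cielab_threshold$dark_L,
    dark_b_threshold = s$cielab_threshold$dark_b,
    dark_dilate_radius = s$artifact_dilation$radius,
    nlm_strength = s$speckle$nlm_strength, nlm_patch = s$speckle$nlm_patch,
    cv_mu = s$chan_vese$mu, cv_max_iter = s$chan_vese$max_iter,
    seg_dilate_radius = s$segmentation_dilation$radius,
    blend_gamma = s$blending$gamma,
    lambda_weight = s$style_transfer$lambda,
    patch_size = st$patch_size, count_mean = st$count_mean,
    cutout_margin = st$cutout_margin,
    max_place_attempts = st$max_place_attempts,
    clip_keep_fraction = st$clip_keep_fraction,
    allow_scaling = st$allow_scaling,
    n_annotated_dishes = st$n_annotated_dishes,
    n_empty_dishes = st$n_empty_dishes, n_styles = st$n_styles,
    style_iterations = st$style_iterations,
    style_learning_rate = st$style_learning_rate,
    style_arch = st$style_arch, patches_per_tile = st$patches_per_tile,
    species_labels = st$species_labels, fixture = fx,
    dishes_dir = doc$dishes_dir)
}

as_extraction_config <- function(cfg) {
  s <- cfg$stages
  extraction_config(
    unsharp_radius = s$unsharp$radius, unsharp_amount = s$unsharp$amount,
    dark_L_threshold = s$cielab_threshold$dark_L,
    dark_b_threshold = s$cielab_threshold$dark_b,
    dark_dilate_radius = s$artifact_dilation$radius,
    nlm_strength = s$speckle$nlm_strength, nlm_patch = s$speckle$nlm_patch,
    cv_mu = s$chan_vese$mu, cv_max_iter = s$chan_vese$max_iter,
    seg_dilate_radius = s$segmentation_dilation$radius,
    blend_gamma = s$blending$gamma,
    cutout_margin = cfg$structural$cutout_margin)
}

as_composition_config <- function(cfg) {
  composition_config(
    patch_size = cfg$structural$patch_size,
    count_mean = cfg$structural$count_mean,
    max_place_attempts = cfg$structural$max_place_attempts,
    clip_keep_fraction = cfg$structural$clip_keep_fraction,
    allow_scaling = cfg$structural$allow_scaling)
}

as_style_config <- function(cfg, lambda) {
  k <- as.integer(sqrt(cfg$structural$patches_per_tile))
  style_config(
    lambda_weight = lambda,
    iterations = cfg$structural$style_iterations,
    learning_rate = cfg$structural$style_learning_rate,
    tile_size = k * cfg$structural$patch_size,
    patches_per_tile = cfg$structural$patches_per_tile,
    arch = cfg$structural$style_arch)
}

read_dish_dir <- function(dir, species_labels) {
  jsons <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  dishes <- lapply(jsons, function(ap) {
    ip <- sub("\\.json$", ".png", ap)
    read_annotated_dish(ip, ap, species_labels = species_labels)
  })
  list(annotated = Filter(function(d) nrow(d$annotations) > 0, dishes),
       empty = Filter(function(d) nrow(d$annotations) == 0, dishes))
}

#' Run the full generation pipeline
#'
#' Resolves input dishes (from `cfg$dishes_dir` or generated fixtures),
#' extracts a cutout bank, composes `n_patches` annotated patches and
#' optionally stylizes them (`semi`: lambda = 0.02; `full`: lambda = 0.05;
#' `raw`: stylization skipped, output identical to composition output).
#' Patches are stylized in tiles of `patches_per_tile`, cycling styles
#' round-robin with warm-started generator weights per style. The written
#' manifest records mode, master seed and a configuration hash; every
#' patch is independently reproducible from `(seed, index)`.
#'
#' @param cfg a [gen_config()].
#' @param n_patches number of patches to generate.
#' @param seed master seed.
#' @param style_mode `"raw"`, `"semi"` or `"full"`.
#' @param out_dir dataset output directory.
#' @param format,overwrite see [write_dataset()].
#' @param verbose emit per-stage log messages?
#' @return manifest path, invisibly.
#' @export
run_pipeline <- function(cfg = gen_config(), n_patches, seed = 1L,
                         style_mode = c("raw", "semi", "full"),
                         out_dir, format = "coco_json", overwrite = FALSE,
                         verbose = FALSE) {
  style_mode <- match.arg(style_mode)
  v <- validate_config(cfg)
  if (length(v$errors)) {
    stop("invalid configuration:\n  ", paste(v$errors, collapse = "\n  "),
         call. = FALSE)
  }
  for (w in v$warnings) warning(w, call. = FALSE)
  log_line <- function(stage, idx, sd) {
    if (verbose) message(sprintf("[%s] patch %s seed %s", stage, idx, sd))
  }
  fail <- function(stage, idx, e) {
    if (dir.exists(out_dir)) {
      writeLines(sprintf("stage %s, patch %s: %s", stage, idx,
                         conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    }
    stop(sprintf("stage %s, patch %s: %s", stage, idx, conditionMessage(e)),
         call. = FALSE)
  }
  labels <- cfg$structural$species_labels
  # ---- inputs ----
  if (!is.null(cfg$dishes_dir)) {
    inp <- read_dish_dir(cfg$dishes_dir, labels)
    annotated <- inp$annotated; empties <- inp$empty
  } else {
    annotated <- lapply(seq_len(cfg$structural$n_annotated_dishes), function(i) {
      make_annotated_dish(cfg$fixture, seed = derive_seed(seed, 300000L + i),
                          species = labels[(i - 1L) %% length(labels) + 1L])$dish
    })
    empties <- lapply(seq_len(cfg$structural$n_empty_dishes), function(i) {
      make_empty_dish(cfg$fixture, seed = derive_seed(seed, 400000L + i))
    })
  }
  if (length(annotated) == 0L || length(empties) == 0L) {
    stop("need at least one annotated and one empty dish", call. = FALSE)
  }
  # ---- extraction ----
  ecfg <- as_extraction_config(cfg)
  bank <- setNames(vector("list", length(labels)), labels)
  for (i in seq_along(annotated)) {
    log_line("extract", i, "-")
    cuts <- tryCatch(
      extract_dish(annotated[[i]], ecfg,
                   overlap_threshold = cfg$stages$clustering$overlap_threshold),
      error = function(e) fail("extract", i, e))
    for (co in cuts) bank[[co$species]] <- c(bank[[co$species]], list(co))
  }
  bank <- bank[lengths(bank) > 0]
  if (length(bank) == 0L) stop("cutout bank is empty", call. = FALSE)
  # ---- composition ----
  ccfg <- as_composition_config(cfg)
  records <- vector("list", n_patches)
  for (i in seq_len(n_patches)) {
    si <- derive_seed(seed, i)
    log_line("compose", i, si)
    records[[i]] <- tryCatch(generate_patch(bank, empties, ccfg, seed = si),
                             error = function(e) fail("compose", i, e))
  }
  # ---- stylization ----
  if (style_mode != "raw") {
    lambda <- if (style_mode == "semi") 0.02 else 0.05
    scfg <- as_style_config(cfg, lambda)
    n_styles <- max(1L, cfg$structural$n_styles)
    styles <- lapply(seq_len(n_styles), function(k) {
      src <- annotated[[(k - 1L) %% length(annotated) + 1L]]
      side <- min(128L, dim(src$image)[1])
      with_seed(derive_seed(seed, 200000L + k), {
        r0 <- sample.int(dim(src$image)[1] - side + 1L, 1L)
        c0 <- sample.int(dim(src$image)[2] - side + 1L, 1L)
        src$image[r0 + seq_len(side) - 1L, c0 + seq_len(side) - 1L, , drop = FALSE]
      })
    })
    ppt <- cfg$structural$patches_per_tile
    warm <- vector("list", n_styles)
    n_tiles <- ceiling(n_patches / ppt)
    for (b in seq_len(n_tiles)) {
      idx <- ((b - 1L) * ppt + 1L):min(b * ppt, n_patches)
      group <- records[idx]
      while (length(group) < ppt) group <- c(group, group[length(group)])
      sid <- (b - 1L) %% n_styles + 1L
      log_line("stylize", paste(range(idx), collapse = "-"), sid)
      res <- tryCatch(
        stylize_batch(group, styles[[sid]], scfg,
                      init_weights = if (scfg$warm_start) warm[[sid]] else NULL,
                      seed = derive_seed(seed, 500000L + b),
                      style_id = sprintf("style_%02d", sid)),
        error = function(e) fail("stylize", paste(idx, collapse = ","), e))
      warm[[sid]] <- res$weights
      records[idx] <- res$records[seq_along(idx)]
    }
  }
  write_dataset(records, out_dir, format = format, overwrite = overwrite,
                extra = list(mode = style_mode, seed = seed,
                             patch_size = cfg$structural$patch_size,
                             config_hash = rlang::hash(list(cfg$stages,
                                                            cfg$structural,
                                                            unclass(cfg$fixture)))))
}
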