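# Patch composition: paste extracted cluster cutouts onto randomly cropped
# empty-dish backgrounds. One species per patch; the colony count follows a
# rounded exponential law; placements are rejection-sampled so footprints
# (alpha > 0, dilated by 1 px) never overlap and always lie fully inside
# the patch.

#' Composition-stage configuration
#'
#' @param patch_size side of the square output patch, pixels.
#' @param count_mean mean of the exponential colonies-per-patch law
#'   (`1/lambda`).
#' @param max_place_attempts rejection-sampling attempts per cluster before
#'   giving up on it.
#' @param clip_keep_fraction a colony whose transformed mask keeps less
#'   than this fraction of its pixels (after clipping) is dropped from the
#'   annotations and erased.
#' @param allow_scaling if `TRUE`, each cutout is additionally scaled by a
#'   uniform factor in `[0.8, 1.25]` (size augmentation; off by default).
#' @param rng_seed default seed for [generate_dataset()].
#' @return list of class `composition_config`.
#' @export
composition_config <- function(patch_size = 512L, count_mean = 10,
                               max_place_attempts = 50L,
                               clip_keep_fraction = 0.3,
                               allow_scaling = FALSE, rng_seed = 1L) {
  stopifnot(patch_size > 0, count_mean > 0, max_place_attempts >= 1)
  structure(list(patch_size = as.integer(patch_size), count_mean = count_mean,
                 max_place_attempts = as.integer(max_place_attempts),
                 clip_keep_fraction = clip_keep_fraction,
                 allow_scaling = allow_scaling,
                 rng_seed = as.integer(rng_seed)),
            class = "composition_config")
}

#' Sample a background crop from an empty dish
#'
#' Rotates the full dish image by a uniform random angle (bilinear
#' interpolation) and crops a uniformly random `size x size` window that
#' contains no out-of-bounds fill pixels.
#'
#' @param empty_dish an `annotated_dish` with no annotations.
#' @param size crop side in pixels.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return `size x size x 3` array.
#' @export
sample_background <- function(empty_dish, size, seed = NULL) {
  draw <- function() {
    angle <- runif(1, 0, 360)
    rot <- rotate_bilinear(empty_dish$image, angle, expand = TRUE,
                           fill = NA_real_)
    valid <- !is.na(rot[, , 1])
    H <- nrow(valid); W <- ncol(valid)
    if (H < size || W < size) {
      stop(sprintf("empty dish too small: need at least %d x %d valid pixels after rotation",
                   size, size), call. = FALSE)
    }
    # integral image over the valid mask -> all fully-valid windows
    S <- rbind(0, cbind(0, t(apply(apply(valid, 2, cumsum), 1, cumsum))))
    nr <- H - size + 1L; ncc <- W - size + 1L
    i1 <- seq_len(nr); j1 <- seq_len(ncc)
    win <- S[i1 + size, j1 + size, drop = FALSE] - S[i1, j1 + size, drop = FALSE] -
      S[i1 + size, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
    ok <- which(win == size * size)
    if (length(ok) == 0L) {
      stop(sprintf("empty dish too small: no fully valid %d x %d window after rotation (image %d x %d)",
                   size, size, W, H), call. = FALSE)
    }
    pick <- ok[sample.int(length(ok), 1L)]
    r0 <- (pick - 1L) %% nr + 1L
    c0 <- (pick - 1L) %/% nr + 1L
    rot[r0:(r0 + size - 1L), c0:(c0 + size - 1L), , drop = FALSE]
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Sample the number of colonies for one patch
#'
#' Draws from an exponential distribution with mean `count_mean`
#' (`lambda = 1/count_mean`) and rounds half-up to a non-negative integer;
#' empty patches are allowed. With `raw = TRUE` the underlying continuous
#' draw is returned (useful for distributional checks).
#'
#' @param n number of draws.
#' @param count_mean mean colonies per patch.
#' @param raw return the continuous exponential draws instead of rounded
#'   counts?
#' @return numeric vector of length `n`.
#' @export
sample_colony_count <- function(n = 1L, count_mean = 10, raw = FALSE) {
  stopifnot(count_mean > 0)
  x <- rexp(n, rate = 1 / count_mean)
  if (raw) x else floor(x + 0.5)
}

# Rotate/flip a cutout's RGB + alpha jointly (premultiplied-alpha bilinear
# interpolation) together with its per-colony masks. Returns the trimmed
# transformed cutout (rows/cols with all-zero alpha at the borders removed).
transform_cutout <- function(cutout, angle, flip_h, flip_v, scale = 1) {
  rgb <- cutout$rgb; alpha <- cutout$alpha
  masks <- cutout$masks
  if (flip_h || flip_v) {
    rgb <- flip_raster(rgb, flip_h, flip_v)
    alpha <- flip_raster(alpha, flip_h, flip_v)
    masks <- lapply(masks, flip_raster, horizontal = flip_h, vertical = flip_v)
  }
  a01 <- alpha / 255
  pre <- rgb
  for (ch in 1:3) pre[, , ch] <- rgb[, , ch] * a01
  stack <- array(0, dim = c(dim(alpha), 4L + length(masks)))
  stack[, , 1:3] <- pre
  stack[, , 4] <- alpha
  for (k in seq_along(masks)) stack[, , 4L + k] <- masks[[k]]
  if (scale != 1) {
    sh <- max(2L, as.integer(round(nrow(alpha) * scale)))
    sw <- max(2L, as.integer(round(ncol(alpha) * scale)))
    stack <- resize_bilinear(stack, sh, sw)
  }
  rot <- rotate_bilinear(stack, angle, expand = TRUE, fill = 0)
  a_t <- rot[, , 4]
  keep_r <- which(rowSums(a_t > 0) > 0)
  keep_c <- which(colSums(a_t > 0) > 0)
  if (length(keep_r) == 0L) return(NULL)
  rot <- rot[min(keep_r):max(keep_r), min(keep_c):max(keep_c), , drop = FALSE]
  a_t <- rot[, , 4]
  rgb_t <- rot[, , 1:3, drop = FALSE]
  nz <- a_t > 0
  for (ch in 1:3) {
    pl <- rgb_t[, , ch]
    pl[nz] <- pl[nz] / (a_t[nz] / 255)
    pl[!nz] <- 0
    rgb_t[, , ch] <- clamp(pl, 0, 255)
  }
  masks_t <- lapply(seq_along(masks), function(k) ((rot[, , 4L + k] > 0) & nz) + 0)
  list(rgb = rgb_t, alpha = a_t, masks = masks_t)
}

resize_bilinear <- function(x, h, w) {
  d <- dim(x)
  ys <- (seq_len(h) - 0.5) * d[1] / h + 0.5
  xs <- (seq_len(w) - 0.5) * d[2] / w + 0.5
  y0 <- clamp(floor(ys), 1, d[1]); y1 <- pmin(y0 + 1, d[1]); fy <- clamp(ys - y0, 0, 1)
  x0 <- clamp(floor(xs), 1, d[2]); x1 <- pmin(x0 + 1, d[2]); fx <- clamp(xs - x0, 0, 1)
  out <- array(0, dim = c(h, w, d[3]))
  FY <- matrix(fy, h, w); FX <- matrix(fx, h, w, byrow = TRUE)
  for (ch in seq_len(d[3])) {
    pl <- x[, , ch]
    out[, , ch] <- (1 - FY) * ((1 - FX) * pl[y0, x0] + FX * pl[y0, x1]) +
      FY * ((1 - FX) * pl[y1, x0] + FX * pl[y1, x1])
  }
  out
}

#' Try to place a cutout on a patch without overlap
#'
#' Samples a rotation in `[0, 360)`, independent horizontal/vertical flips
#' and a uniform position, and accepts the first proposal whose transformed
#' footprint (`alpha > 0`, dilated by 1 px) lies fully inside the patch and
#' is disjoint from every previously placed footprint. A cutout whose tight
#' alpha box (at the smallest sampled scale) cannot fit the patch at all is
#' rejected immediately without spending attempts; colony footprints are
#' compact, so a rotation that shrinks the bounding box enough to rescue
#' such a cutout does not occur in practice.
#'
#' @param occupancy 0/1 matrix of already-claimed pixels (patch geometry).
#' @param cutout a `cluster_cutout`.
#' @param max_attempts rejection budget.
#' @param allow_scaling sample a scale factor in `[0.8, 1.25]`?
#' @return `NULL` on failure, else a list with the transformed cutout
#'   (`rgb`, `alpha`, `masks`), `row`/`col` (0-based top-left in patch
#'   coordinates), `angle`, `flip_h`, `flip_v`, `scale`, `footprint`.
#' @export
try_place <- function(occupancy, cutout, max_attempts = 50L,
                      allow_scaling = FALSE) {
  S <- nrow(occupancy)
  # fast infeasibility check: the rotated footprint's bounding box is never
  # smaller than the footprint's own tight box, so a cutout whose tight
  # alpha box (plus the 1-px margin) exceeds the patch can never be placed
  tb <- mask_tight_bbox(cutout$alpha)
  if (is.null(tb)) return(NULL)
  if (max(tb$w, tb$h) * (if (allow_scaling) 0.8 else 1) + 2 > S) return(NULL)
  for (att in seq_len(max_attempts)) {
    angle <- runif(1, 0, 360)
    flip_h <- runif(1) < 0.5
    flip_v <- runif(1) < 0.5
    scale <- if (allow_scaling) runif(1, 0.8, 1.25) else 1
    tc <- transform_cutout(cutout, angle, flip_h, flip_v, scale)
    if (is.null(tc)) next
    h <- nrow(tc$alpha); w <- ncol(tc$alpha)
    if (h + 2L > S || w + 2L > S) next # dilated footprint must fit the patch
    # pad by 1 px before dilating: the trimmed alpha touches its own frame,
    # so the 1-px safety margin lives in the padded geometry (h+2) x (w+2)
    fp_pad <- matrix(0, h + 2L, w + 2L)
    fp_pad[1L + seq_len(h), 1L + seq_len(w)] <- (tc$alpha > 0) + 0
    fp_pad <- dilate_mask(fp_pad, 1)
    r0 <- 1L + sample.int(S - h - 1L, 1L) # 1-based top row of the cutout, >= 2
    c0 <- 1L + sample.int(S - w - 1L, 1L)
    win <- occupancy[(r0 - 1L):(r0 + h), (c0 - 1L):(c0 + w)]
    if (any(win * fp_pad > 0)) next
    return(list(cutout = tc, row = r0 - 1L, col = c0 - 1L, angle = angle,
                flip_h = flip_h, flip_v = flip_v, scale = scale,
                footprint = fp_pad))
  }
  NULL
}

#' Alpha-composite a placed cutout onto a patch
#'
#' Standard "over" blend with `alpha / 255` as per-pixel opacity.
#'
#' @param patch `S x S x 3` background.
#' @param placed result of [try_place()].
#' @return updated patch.
#' @export
blend_patch <- function(patch, placed) {
  tc <- placed$cutout
  h <- nrow(tc$alpha); w <- ncol(tc$alpha)
  rows <- placed$row + seq_len(h); cols <- placed$col + seq_len(w)
  a <- tc$alpha / 255
  for (ch in 1:3) {
    region <- patch[rows, cols, ch]
    patch[rows, cols, ch] <- round(a * tc$rgb[, , ch] + (1 - a) * region)
  }
  patch
}

#' Generate one annotated synthetic patch
#'
#' Samples one species, a target colony count from the exponential law and
#' a background crop, then places cluster cutouts (drawn with replacement
#' from the bank) until the cumulative colony count reaches the target or
#' the placement budget (10 cluster draws per target colony) is exhausted;
#' five consecutive completely-failed draws end placement early, since a
#' patch that rejects that many clusters across all their attempts is
#' effectively full. Each instance's bounding box is recomputed as the
#' tight box of its transformed mask.
#'
#' @param bank named list: species label -> list of `cluster_cutout`s.
#' @param empty_dishes list of empty `annotated_dish`es.
#' @param cfg a [composition_config()].
#' @param seed RNG seed for this patch.
#' @return a `synth_patch_record` (image, annotations, masks, provenance).
#' @export
generate_patch <- function(bank, empty_dishes, cfg = composition_config(),
                           seed = 1L) {
  stopifnot(length(bank) > 0, length(empty_dishes) > 0)
  with_seed(seed, {
    species <- sample(names(bank), 1L)
    if (length(bank[[species]]) == 0L) {
      stop("cutout bank is empty for species ", species, call. = FALSE)
    }
    target <- sample_colony_count(1L, cfg$count_mean)
    dish_i <- sample.int(length(empty_dishes), 1L)
    # rounded to whole intensities: records are 8-bit rasters end to end
    patch <- round(sample_background(empty_dishes[[dish_i]], cfg$patch_size))
    S <- cfg$patch_size
    occupancy <- matrix(0, S, S)
    ann <- empty_annotations()
    masks <- list()
    placed_colonies <- 0L
    budget <- 10L * max(1L, as.integer(target))
    draws <- 0L
    failed_run <- 0L
    while (placed_colonies < target && draws < budget && failed_run < 5L) {
      draws <- draws + 1L
      co <- bank[[species]][[sample.int(length(bank[[species]]), 1L)]]
      pl <- try_place(occupancy, co, cfg$max_place_attempts, cfg$allow_scaling)
      if (is.null(pl)) { failed_run <- failed_run + 1L; next }
      failed_run <- 0L
      patch <- blend_patch(patch, pl)
      h <- nrow(pl$cutout$alpha); w <- ncol(pl$cutout$alpha)
      rows <- pl$row + seq_len(h); cols <- pl$col + seq_len(w)
      # claim the dilated footprint (padded geometry) so placed footprints
      # stay pairwise disjoint even after each side's 1-px dilation
      prow <- (pl$row):(pl$row + h + 1L); pcol <- (pl$col):(pl$col + w + 1L)
      occupancy[prow, pcol] <- pmax(occupancy[prow, pcol], pl$footprint)
      for (k in seq_along(pl$cutout$masks)) {
        full <- matrix(0, S, S)
        full[rows, cols] <- pl$cutout$masks[[k]]
        tb <- mask_tight_bbox(full)
        if (is.null(tb)) next
        kept <- sum(full) / max(1, sum(pl$cutout$masks[[k]]))
        if (kept < cfg$clip_keep_fraction) {
          next # dropped: too little of the colony survived clipping
        }
        masks[[length(masks) + 1L]] <- full
        ann <- rbind(ann, data.frame(instance_id = length(masks),
                                     x = tb$x, y = tb$y, w = tb$w, h = tb$h,
                                     species = species))
        placed_colonies <- placed_colonies + 1L
      }
    }
    rownames(ann) <- NULL
    new_synth_patch_record(patch, ann, masks,
                           provenance = list(
                             empty_dish = empty_dishes[[dish_i]]$source_id,
                             style = "raw", seed = seed))
  })
}

#' Generate and write a dataset of synthetic patches
#'
#' Per-patch seeds are derived from `(seed, patch index)` with
#' [derive_seed()], so any single patch can be regenerated independently
#' and the whole run is byte-reproducible under the same `(seed, cfg)`.
#'
#' @inheritParams generate_patch
#' @param n_patches number of patches.
#' @param seed master seed.
#' @param out_dir output directory; see [write_dataset()].
#' @param format dataset format; see [write_dataset()].
#' @param overwrite passed to [write_dataset()].
#' @return manifest path, invisibly.
#' @export
generate_dataset <- function(bank, empty_dishes, cfg = composition_config(),
                             n_patches = 1L, seed = 1L, out_dir,
                             format = "coco_json", overwrite = FALSE) {
  stopifnot(n_patches >= 1)
  records <- lapply(seq_len(n_patches), function(i) {
    tryCatch(
      generate_patch(bank, empty_dishes, cfg, seed = derive_seed(seed, i)),
      error = function(e) {
        stop(sprintf("patch %d failed: %s", i, conditionMessage(e)),
             call. = FALSE)
      })
  })
  write_dataset(records, out_dir, format = format, overwrite = overwrite,
                extra = list(seed = seed, patch_size = cfg$patch_size))
}
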