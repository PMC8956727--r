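# Programmatic pseudo-real dish fixtures: top-view circular dishes with
# soft-edged, species-colored colony blobs (optionally overlapping), dark
# text-like substrate artifacts, lighting gradients and pixel noise, plus
# exact ground-truth masks. They exist so the whole pipeline can be built
# and tested without any external dish photographs; they are not meant to
# be photorealistic.

#' Fixture-generator configuration
#'
#' @param dish_diameter dish diameter in pixels. The default (760) matches
#'   the working scale of 512-px patches: colonies are a dozen pixels
#'   across, as they are when a full plate photograph is tiled into
#'   patches.
#' @param n_colonies colonies per annotated dish.
#' @param colony_radius_range min/max colony radius, pixels.
#' @param overlap_probability probability that a colony is deliberately
#'   placed against an earlier one so their boxes overlap.
#' @param artifact_text stamp dark text-like glyphs on the substrate?
#' @param lighting_gradient relative amplitude of a linear lighting ramp.
#' @param noise_sigma Gaussian pixel-noise standard deviation (intensity
#'   units, 0..255 scale).
#' @param rng_seed default seed.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(dish_diameter = 760, n_colonies = 8,
                           colony_radius_range = c(7, 14),
                           overlap_probability = 0.15,
                           artifact_text = TRUE, lighting_gradient = 0.15,
                           noise_sigma = 2, rng_seed = 1L) {
  stopifnot(dish_diameter > 4 * max(colony_radius_range),
            overlap_probability >= 0, overlap_probability <= 1,
            lighting_gradient >= 0, lighting_gradient <= 1,
            noise_sigma >= 0)
  structure(list(dish_diameter = dish_diameter,
                 n_colonies = as.integer(n_colonies),
                 colony_radius_range = colony_radius_range,
                 overlap_probability = overlap_probability,
                 artifact_text = artifact_text,
                 lighting_gradient = lighting_gradient,
                 noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_config")
}

# per-species rendering palette: RGB color, extra blur sigma, radius scale
species_palette <- function() {
  list(
    "B.subtilis"   = list(color = c(206, 196, 172), blur = 1.0, rscale = 1.0),
    "C.albicans"   = list(color = c(236, 233, 226), blur = 0.8, rscale = 1.0),
    "E.coli"       = list(color = c(202, 182, 142), blur = 1.0, rscale = 0.9),
    "P.aeruginosa" = list(color = c(176, 189, 158), blur = 1.8, rscale = 1.1),
    "S.aureus"     = list(color = c(224, 203, 118), blur = 0.5, rscale = 0.7))
}

#' Generate an empty fixture dish
#'
#' A bright circular agar disk with a darker rim on a dark surround, a
#' linear lighting gradient in a random direction, and Gaussian pixel
#' noise. The annotation list is empty.
#'
#' @param cfg a [fixture_config()].
#' @param seed RNG seed.
#' @return an `annotated_dish` with zero annotations.
#' @export
make_empty_dish <- function(cfg = fixture_config(), seed = cfg$rng_seed) {
  with_seed(seed, {
    side <- as.integer(ceiling(cfg$dish_diameter * 1.15))
    R <- cfg$dish_diameter / 2
    cy <- (side + 1) / 2; cx <- (side + 1) / 2
    yy <- matrix(seq_len(side) - cy, side, side)
    xx <- matrix(seq_len(side) - cx, side, side, byrow = TRUE)
    r <- sqrt(yy^2 + xx^2)
    agar <- c(190, 180, 163)
    rim <- c(95, 92, 88)
    outside <- c(45, 45, 48)
    img <- array(0, dim = c(side, side, 3L))
    inner <- r <= 0.94 * R
    ring <- r > 0.94 * R & r <= R
    for (ch in 1:3) {
      pl <- matrix(outside[ch], side, side)
      pl[ring] <- rim[ch]
      pl[inner] <- agar[ch]
      img[, , ch] <- pl
    }
    # smooth the dish edge a little
    img <- blur_gaussian(img, 1.2)
    theta <- runif(1, 0, 2 * pi)
    proj <- (cos(theta) * xx + sin(theta) * yy) / side
    ramp <- 1 + cfg$lighting_gradient * 2 * proj
    for (ch in 1:3) img[, , ch] <- img[, , ch] * ramp
    if (cfg$noise_sigma > 0) {
      img <- img + array(rnorm(length(img), sd = cfg$noise_sigma), dim = dim(img))
    }
    new_annotated_dish(clamp(round(img), 0, 255), empty_annotations(),
                       source_id = sprintf("fixture_empty_%d", seed))
  })
}

# Draw a dark stroke of the given half-thickness along a segment.
draw_stroke <- function(img, p0, p1, color, thickness = 1) {
  n <- max(2L, as.integer(ceiling(sqrt(sum((p1 - p0)^2)) * 2)))
  t <- seq(0, 1, length.out = n)
  ys <- round(p0[1] + t * (p1[1] - p0[1]))
  xs <- round(p0[2] + t * (p1[2] - p0[2]))
  H <- dim(img)[1]; W <- dim(img)[2]
  for (dy in -thickness:thickness) {
    for (dx in -thickness:thickness) {
      yy <- clamp(ys + dy, 1, H); xx <- clamp(xs + dx, 1, W)
      for (ch in 1:3) img[cbind(yy, xx, ch)] <- color[ch]
    }
  }
  img
}

#' Generate an annotated fixture dish with ground truth
#'
#' Builds on [make_empty_dish()]: renders `n_colonies` soft-edged
#' anisotropic colonies of a single species (as on real plates), forcing
#' bounding-box overlap with probability `overlap_probability`, optionally
#' stamps dark text-like artifacts on the substrate away from colonies,
#' and returns tight bounding boxes plus exact per-colony ground-truth
#' masks.
#'
#' @param cfg a [fixture_config()].
#' @param seed RNG seed.
#' @param species species label; sampled uniformly when `NULL`.
#' @return list with `dish` (an `annotated_dish`) and `truth_masks` (one
#'   entry per colony: list with `offset = c(row0, col0)` (0-based) and a
#'   local 0/1 `mask`).
#' @export
make_annotated_dish <- function(cfg = fixture_config(), seed = cfg$rng_seed,
                                species = NULL) {
  empty <- make_empty_dish(cfg, seed)
  with_seed(seed + 1L, {
    img <- empty$image
    side <- dim(img)[1]
    R <- cfg$dish_diameter / 2
    cyx <- (side + 1) / 2
    sp <- species %||% sample(agar_species(), 1L)
    pal <- species_palette()[[sp]]
    rr <- cfg$colony_radius_range * pal$rscale
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    ann <- empty_annotations()
    truth <- list()
    for (i in seq_len(cfg$n_colonies)) {
      r_i <- runif(1, rr[1], rr[2])
      placed <- FALSE
      for (try in 1:200) {
        if (i > 1 && runif(1) < cfg$overlap_probability) {
          j <- sample.int(i - 1L, 1L)
          phi <- runif(1, 0, 2 * pi)
          dist <- 0.75 * (r_i + radii[j])
          cen <- centers[j, ] + dist * c(sin(phi), cos(phi))
        } else {
          phi <- runif(1, 0, 2 * pi)
          rad <- sqrt(runif(1)) * (0.8 * R - 3 * r_i)
          cen <- cyx + rad * c(sin(phi), cos(phi))
          if (i > 1) {
            d <- sqrt(rowSums((centers - matrix(cen, i - 1L, 2, byrow = TRUE))^2))
            if (any(d < 1.6 * (radii + r_i))) next
          }
        }
        if (sqrt(sum((cen - cyx)^2)) > 0.85 * R - 1.5 * r_i) next
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("cannot fit ", cfg$n_colonies,
             " colonies inside the dish; reduce colony_radius_range or n_colonies",
             call. = FALSE)
      }
      centers <- rbind(centers, cen)
      radii <- c(radii, r_i)
      # render into a local window
      ext <- ceiling(3 * r_i)
      y0 <- max(1L, as.integer(floor(cen[1] - ext)))
      x0 <- max(1L, as.integer(floor(cen[2] - ext)))
      y1 <- min(side, as.integer(ceiling(cen[1] + ext)))
      x1 <- min(side, as.integer(ceiling(cen[2] + ext)))
      wy <- matrix(y0:y1 - cen[1], y1 - y0 + 1L, x1 - x0 + 1L)
      wx <- matrix(x0:x1 - cen[2], y1 - y0 + 1L, x1 - x0 + 1L, byrow = TRUE)
      ar <- runif(1, 0.75, 1)
      th <- runif(1, 0, pi)
      u <- cos(th) * wx + sin(th) * wy
      v <- -sin(th) * wx + cos(th) * wy
      g <- exp(-0.5 * ((u / r_i)^2 + (v / (r_i * ar))^2) * 2.2)
      profile <- 0.45 * (g > 0.2) + 0.35 * (g > 0.45) + 0.2 * (g > 0.75)
      profile <- blur_gaussian(profile, pal$blur)
      jitter <- rnorm(3, sd = 4)
      for (ch in 1:3) {
        win <- img[y0:y1, x0:x1, ch]
        img[y0:y1, x0:x1, ch] <- win * (1 - profile) +
          (pal$color[ch] + jitter[ch]) * profile
      }
      mask <- (g > 0.2) + 0
      tb <- mask_tight_bbox(mask)
      ann <- rbind(ann, data.frame(instance_id = i,
                                   x = tb$x + x0 - 1, y = tb$y + y0 - 1,
                                   w = tb$w, h = tb$h, species = sp))
      truth[[i]] <- list(offset = c(y0 - 1L, x0 - 1L), mask = mask)
    }
    if (cfg$artifact_text) {
      ink <- c(25, 25, 32) # L* well below the default dark threshold
      n_marks <- sample(2:4, 1L)
      boxes_infl <- ann
      for (k in seq_len(n_marks)) {
        for (try in 1:50) {
          phi <- runif(1, 0, 2 * pi)
          rad <- sqrt(runif(1)) * 0.75 * R
          p0 <- cyx + rad * c(sin(phi), cos(phi))
          len <- runif(1, 8, 22)
          dir <- runif(1, 0, 2 * pi)
          p1 <- p0 + len * c(sin(dir), cos(dir))
          lo <- pmin(p0, p1) - 6; hi <- pmax(p0, p1) + 6
          clash <- any(boxes_infl$x - 6 < hi[2] & boxes_infl$x + boxes_infl$w + 6 > lo[2] &
                         boxes_infl$y - 6 < hi[1] & boxes_infl$y + boxes_infl$h + 6 > lo[1])
          if (!clash && sqrt(sum((p1 - cyx)^2)) < 0.85 * R) {
            img <- draw_stroke(img, p0, p1, ink, thickness = 1)
            break
          }
        }
      }
    }
    if (cfg$noise_sigma > 0) {
      img <- clamp(round(img +
                           array(rnorm(length(img), sd = cfg$noise_sigma / 2),
                                 dim = dim(img))), 0, 255)
    }
    rownames(ann) <- NULL
    dish <- new_annotated_dish(img, ann,
                               source_id = sprintf("fixture_dish_%d", seed))
    list(dish = dish, truth_masks = truth)
  })
}

#' Write a set of fixture dishes to disk
#'
#' Writes `n_dishes` annotated dishes plus `n_empty` empty dishes in the
#' input dialect of [read_annotated_dish()] (PNG + JSON). Species cycle
#' deterministically so every label is covered when `n_dishes >= 5`.
#'
#' @param out_dir output directory.
#' @param n_dishes annotated dish count.
#' @param n_empty empty dish count.
#' @param cfg a [fixture_config()].
#' @param seed master seed.
#' @return invisibly, a data.frame of written file paths.
#' @export
write_fixture_set <- function(out_dir, n_dishes = 10L, n_empty = 10L,
                              cfg = fixture_config(), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- agar_species()
  files <- data.frame(image = character(), annotation = character())
  for (i in seq_len(n_dishes)) {
    fx <- make_annotated_dish(cfg, seed = derive_seed(seed, i),
                              species = labels[(i - 1L) %% length(labels) + 1L])
    ip <- file.path(out_dir, sprintf("dish_%03d.png", i))
    ap <- file.path(out_dir, sprintf("dish_%03d.json", i))
    write_annotated_dish(fx$dish, ip, ap)
    files <- rbind(files, data.frame(image = ip, annotation = ap))
  }
  for (i in seq_len(n_empty)) {
    dish <- make_empty_dish(cfg, seed = derive_seed(seed, 100000L + i))
    ip <- file.path(out_dir, sprintf("empty_%03d.png", i))
    ap <- file.path(out_dir, sprintf("empty_%03d.json", i))
    write_annotated_dish(dish, ip, ap)
    files <- rbind(files, data.frame(image = ip, annotation = ap))
  }
  invisible(files)
}
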