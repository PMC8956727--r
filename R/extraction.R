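# Colony-cluster extraction: cut a rectangular fragment around each cluster
# of overlapping colonies, scrub dark substrate artifacts (printed text,
# contamination), denoise, segment the colonies with a level set, and build
# the cutout's alpha channel as the Hadamard product of three masks:
#   m_bx  - 1 on the union of the cluster's bounding boxes, 0 elsewhere
#   m_s   - binary colony segmentation (dilated so edges are kept)
#   m_b   - blending mask in [0, 255], proportional to each pixel's CIELab
#           distance from the average background color
# alpha = m_bx o m_s o m_b.

#' Extraction-stage configuration
#'
#' Tunable parameters of the colony-extraction chain (the clustering
#' threshold lives in [build_adjacency()] / [gen_config()]).
#'
#' @param unsharp_radius Gaussian sigma of the unsharp mask, pixels.
#' @param unsharp_amount unsharp strength (0 disables).
#' @param dark_L_threshold CIELab L* below which a pixel is a dark
#'   artifact candidate (L* scale 0-100).
#' @param dark_b_threshold CIELab b* below which a pixel is an artifact
#'   candidate (dark bluish ink/text has negative b*).
#' @param dark_dilate_radius dilation radius of the artifact mask, pixels.
#' @param nlm_strength non-local-means filter strength (intensity units).
#' @param nlm_patch non-local-means patch size, pixels (odd).
#' @param cv_mu Chan-Vese contour-length weight.
#' @param cv_max_iter Chan-Vese iteration cap.
#' @param seg_dilate_radius dilation radius of the segmentation mask,
#'   pixels (margins so whole colonies survive, edges included).
#' @param blend_gamma exponent applied to the normalized CIELab background
#'   distance before scaling to `[0, 255]`; 1 = plain proportionality.
#' @param cutout_margin margin around the cluster's box union, pixels.
#' @param rng_seed seed for the randomized steps (artifact random walk).
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(unsharp_radius = 2, unsharp_amount = 1,
                              dark_L_threshold = 40, dark_b_threshold = -5,
                              dark_dilate_radius = 2,
                              nlm_strength = 8, nlm_patch = 3,
                              cv_mu = 0.25, cv_max_iter = 200L,
                              seg_dilate_radius = 2, blend_gamma = 1,
                              cutout_margin = 4, rng_seed = 1L) {
  stopifnot(unsharp_radius >= 0, dark_dilate_radius >= 0,
            seg_dilate_radius >= 0, cutout_margin >= 0, cv_max_iter >= 1)
  structure(list(unsharp_radius = unsharp_radius,
                 unsharp_amount = unsharp_amount,
                 dark_L_threshold = dark_L_threshold,
                 dark_b_threshold = dark_b_threshold,
                 dark_dilate_radius = dark_dilate_radius,
                 nlm_strength = nlm_strength, nlm_patch = nlm_patch,
                 cv_mu = cv_mu, cv_max_iter = as.integer(cv_max_iter),
                 seg_dilate_radius = seg_dilate_radius,
                 blend_gamma = blend_gamma,
                 cutout_margin = cutout_margin,
                 rng_seed = as.integer(rng_seed)),
            class = "extraction_config")
}

#' Cut the rectangular fragment holding one colony cluster
#'
#' The fragment is the union bounding rectangle of the cluster's boxes,
#' expanded by `margin` and clipped to the image. `m_bx` is 1 exactly on
#' pixels covered by at least one member box.
#'
#' @param dish an `annotated_dish`.
#' @param cluster integer vector of annotation row indices (one connected
#'   cluster).
#' @param margin margin in pixels.
#' @return list with `rgb` (fragment), `m_bx`, `boxes` (member boxes in
#'   fragment-local 0-based coordinates) and `offset` (`c(row0, col0)`
#'   0-based fragment origin in the dish).
#' @export
cut_cluster <- function(dish, cluster, margin = 0) {
  stopifnot(length(cluster) >= 1, margin >= 0)
  ann <- dish$annotations[cluster, , drop = FALSE]
  H <- dim(dish$image)[1]; W <- dim(dish$image)[2]
  x0 <- max(0, floor(min(ann$x) - margin))
  y0 <- max(0, floor(min(ann$y) - margin))
  x1 <- min(W, ceiling(max(ann$x + ann$w) + margin))
  y1 <- min(H, ceiling(max(ann$y + ann$h) + margin))
  if (x0 > min(ann$x) - margin || y0 > min(ann$y) - margin ||
      x1 < max(ann$x + ann$w) + margin || y1 < max(ann$y + ann$h) + margin) {
    message("cut_cluster: margin truncated at the image border")
  }
  frag <- dish$image[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  local <- data.frame(instance_id = ann$instance_id,
                      x = ann$x - x0, y = ann$y - y0,
                      w = ann$w, h = ann$h, species = ann$species)
  m_bx <- matrix(0, nrow(frag), ncol(frag))
  for (i in seq_len(nrow(local))) m_bx <- rasterize_box(m_bx, local[i, ])
  list(rgb = frag, m_bx = m_bx, boxes = local, offset = c(y0, x0))
}

#' Detect and inpaint dark substrate artifacts
#'
#' Dark text labels and contamination are detected by thresholding in
#' CIELab (`L* < dark_L_threshold` OR `b* < dark_b_threshold`), the mask is
#' dilated, and every masked pixel is replaced by the value of the first
#' valid (unmasked) pixel reached by a seeded uniform 8-neighborhood random
#' walk over the frozen input image. Walks are capped at 10x the fragment
#' perimeter; a capped walk falls back to the nearest valid pixel by
#' Euclidean distance. Pixels outside the mask are returned bit-exactly.
#'
#' @param rgb fragment (`H x W x 3`, 0..255), already unsharp-filtered.
#' @param cfg an [extraction_config()].
#' @return list with `rgb` (cleaned fragment) and `m_d` (0/1 artifact
#'   mask).
#' @export
remove_dark_artifacts <- function(rgb, cfg) {
  lab <- srgb_to_lab(rgb)
  raw <- (lab[, , 1] < cfg$dark_L_threshold) | (lab[, , 3] < cfg$dark_b_threshold)
  m_d <- dilate_mask(raw + 0, cfg$dark_dilate_radius)
  if (all(m_d > 0)) stop("no valid pixels for replacement: artifact mask covers the whole fragment",
                         call. = FALSE)
  if (!any(m_d > 0)) return(list(rgb = rgb, m_d = m_d))
  H <- nrow(m_d); W <- ncol(m_d)
  out <- rgb
  bad <- which(m_d > 0, arr.ind = TRUE)
  good_idx <- which(m_d == 0, arr.ind = TRUE)
  cap <- 10L * as.integer(2 * (H + W))
  moves <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  with_seed(cfg$rng_seed, {
    for (p in seq_len(nrow(bad))) {
      r <- bad[p, 1]; c <- bad[p, 2]
      donor <- NULL
      steps <- 0L
      rr <- r; cc <- c
      while (steps < cap) {
        k <- sample.int(8L, 1L)
        nr <- rr + moves[k, 1]; nc <- cc + moves[k, 2]
        if (nr < 1 || nr > H || nc < 1 || nc > W) { steps <- steps + 1L; next }
        rr <- nr; cc <- nc
        steps <- steps + 1L
        if (m_d[rr, cc] == 0) { donor <- c(rr, cc); break }
      }
      if (is.null(donor)) {
        d2 <- (good_idx[, 1] - r)^2 + (good_idx[, 2] - c)^2
        donor <- good_idx[which.min(d2), ]
      }
      out[r, c, ] <- rgb[donor[1], donor[2], ]
    }
  })
  list(rgb = out, m_d = m_d)
}

#' Denoise a fragment with non-local means
#'
#' Thin wrapper applying the configured strength/patch; see
#' [nlm_denoise()].
#'
#' @inheritParams remove_dark_artifacts
#' @return denoised fragment.
#' @export
denoise_fragment <- function(rgb, cfg) {
  nlm_denoise(rgb, strength = cfg$nlm_strength, patch = cfg$nlm_patch)
}

#' Segment colonies in a cleaned fragment
#'
#' Runs Chan-Vese on the luminance channel (checkerboard initialization,
#' at most `cv_max_iter` iterations), picks as foreground the phase whose
#' mean luminance differs more from the fragment-border mean, and dilates
#' the result by `seg_dilate_radius` so whole colonies are kept together
#' with their edges. A constant fragment yields an empty mask with a
#' warning.
#'
#' @inheritParams remove_dark_artifacts
#' @return 0/1 segmentation mask `m_s`.
#' @export
segment_chan_vese <- function(rgb, cfg) {
  lum <- luminance01(rgb)
  if (diff(range(lum)) == 0) {
    warning("constant fragment: no separable phases, returning empty mask",
            call. = FALSE)
    return(matrix(0, nrow(lum), ncol(lum)))
  }
  cv <- chan_vese(lum, mu = cfg$cv_mu, max_iter = cfg$cv_max_iter)
  seg <- cv$segmentation
  border <- c(lum[1, ], lum[nrow(lum), ], lum[, 1], lum[, ncol(lum)])
  mb <- mean(border)
  m_in <- if (any(seg)) mean(lum[seg]) else mb
  m_out <- if (any(!seg)) mean(lum[!seg]) else mb
  fg <- if (abs(m_in - mb) >= abs(m_out - mb)) seg else !seg
  dilate_mask(fg + 0, cfg$seg_dilate_radius)
}

#' Distance-to-background blending mask
#'
#' For each pixel, the Euclidean CIELab distance to the mean background
#' color (mean over pixels outside `m_s`), normalized by the fragment
#' maximum, optionally raised to `blend_gamma`, and scaled to `[0, 255]`.
#' Pixels similar to the background get low opacity so pasted cutouts
#' blend into new backgrounds.
#'
#' @inheritParams remove_dark_artifacts
#' @param m_s 0/1 segmentation mask; must leave some background pixels.
#' @return integer-valued matrix `m_b` in `[0, 255]`.
#' @export
blending_mask <- function(rgb, m_s, cfg = extraction_config()) {
  if (all(m_s > 0)) stop("no background sample: segmentation mask covers the whole fragment",
                         call. = FALSE)
  lab <- srgb_to_lab(rgb)
  bg <- m_s == 0
  cbar <- c(mean(lab[, , 1][bg]), mean(lab[, , 2][bg]), mean(lab[, , 3][bg]))
  d <- sqrt((lab[, , 1] - cbar[1])^2 + (lab[, , 2] - cbar[2])^2 +
              (lab[, , 3] - cbar[3])^2)
  dmax <- max(d)
  if (dmax == 0) return(matrix(0, nrow(d), ncol(d)))
  round(255 * (d / dmax)^cfg$blend_gamma)
}

#' Compose the final alpha channel
#'
#' `alpha = m_bx o m_s o m_b` (element-wise), with the binary masks acting
#' as 0/1 factors and `m_b` carrying the `[0, 255]` scale.
#'
#' @param m_bx,m_s 0/1 matrices.
#' @param m_b matrix in `[0, 255]`.
#' @return alpha matrix in `[0, 255]`.
#' @export
compose_alpha <- function(m_bx, m_s, m_b) {
  if (!identical(dim(m_bx), dim(m_s)) || !identical(dim(m_s), dim(m_b))) {
    stop("mask shapes differ", call. = FALSE)
  }
  (m_bx > 0) * (m_s > 0) * m_b
}

#' Extract one colony cluster as an RGBA cutout
#'
#' Full chain: [cut_cluster()] -> [unsharp_mask()] ->
#' [remove_dark_artifacts()] -> [denoise_fragment()] ->
#' [segment_chan_vese()] -> [blending_mask()] -> [compose_alpha()].
#' Per-colony instance masks are `alpha > 0` restricted to each colony's
#' fragment-local box. A cluster whose alpha is entirely zero is rejected
#' (returns `NULL` with a warning) so it never enters the cutout bank.
#'
#' @param dish an `annotated_dish`.
#' @param cluster integer vector of annotation indices.
#' @param cfg an [extraction_config()].
#' @return a `cluster_cutout` (list with `rgb`, `m_bx`, `m_d`, `m_s`,
#'   `m_b`, `alpha`, `boxes`, `masks`, `species`) or `NULL`.
#' @export
extract_cluster <- function(dish, cluster, cfg = extraction_config()) {
  cut <- cut_cluster(dish, cluster, margin = cfg$cutout_margin)
  sharp <- unsharp_mask(cut$rgb, cfg$unsharp_radius, cfg$unsharp_amount)
  cleaned <- remove_dark_artifacts(sharp, cfg)
  den <- denoise_fragment(cleaned$rgb, cfg)
  m_s <- segment_chan_vese(den, cfg)
  if (!any(m_s > 0)) {
    warning("cluster rejected: empty segmentation", call. = FALSE)
    return(NULL)
  }
  m_b <- blending_mask(den, m_s, cfg)
  alpha <- compose_alpha(cut$m_bx, m_s, m_b)
  if (!any(alpha > 0)) {
    warning("cluster rejected: alpha channel entirely zero", call. = FALSE)
    return(NULL)
  }
  masks <- lapply(seq_len(nrow(cut$boxes)), function(i) {
    box_mask <- rasterize_box(matrix(0, nrow(alpha), ncol(alpha)), cut$boxes[i, ])
    (alpha > 0) * box_mask
  })
  structure(list(rgb = den, m_bx = cut$m_bx, m_d = cleaned$m_d, m_s = m_s,
                 m_b = m_b, alpha = alpha, boxes = cut$boxes, masks = masks,
                 species = cut$boxes$species[1], offset = cut$offset),
            class = "cluster_cutout")
}

#' Extract every cluster of a dish into a cutout list
#'
#' Convenience wrapper: builds the adjacency graph, finds clusters and
#' extracts each one, silently skipping rejected clusters.
#'
#' @param dish an `annotated_dish`.
#' @param cfg an [extraction_config()].
#' @param overlap_threshold clustering threshold (see
#'   [build_adjacency()]).
#' @return list of `cluster_cutout`s.
#' @export
extract_dish <- function(dish, cfg = extraction_config(),
                         overlap_threshold = 0.01) {
  if (nrow(dish$annotations) == 0L) return(list())
  adj <- build_adjacency(dish$annotations, threshold = overlap_threshold)
  clusters <- connected_clusters(adj)
  out <- list()
  for (cl in clusters) {
    co <- withCallingHandlers(
      extract_cluster(dish, cl, cfg),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!is.null(co)) out[[length(out) + 1L]] <- co
  }
  out
}
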