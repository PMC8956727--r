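# Low-level raster helpers shared by extraction and composition.
# Convention: images are numeric arrays H x W (x C) on the 0..255 scale,
# row 1 = top of the image; masks are numeric 0/1 matrices.

pad_replicate <- function(mat, k) {
  if (k == 0) return(mat)
  ri <- c(rep(1L, k), seq_len(nrow(mat)), rep(nrow(mat), k))
  ci <- c(rep(1L, k), seq_len(ncol(mat)), rep(ncol(mat), k))
  mat[ri, ci, drop = FALSE]
}

pad_reflect <- function(mat, k) {
  if (k == 0) return(mat)
  n <- nrow(mat); m <- ncol(mat)
  ri <- c(rev(seq_len(min(k, n))), seq_len(n), n + 1 - rev(seq_len(min(k, n))))
  if (k > n) ri <- rep(ri, length.out = n + 2 * k) # degenerate tiny inputs
  ci <- c(rev(seq_len(min(k, m))), seq_len(m), m + 1 - rev(seq_len(min(k, m))))
  if (k > m) ci <- rep(ci, length.out = m + 2 * k)
  mat[ri, ci, drop = FALSE]
}

# Separable Gaussian blur with replicate boundaries.
blur_gaussian <- function(x, sigma) {
  if (sigma <= 0) return(x)
  if (length(dim(x)) == 3L) {
    out <- x
    for (ch in seq_len(dim(x)[3])) out[, , ch] <- blur_gaussian(x[, , ch], sigma)
    return(out)
  }
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_replicate(x, r)
  n <- nrow(x); m <- ncol(x)
  # rows
  acc <- matrix(0, n, m + 2 * r)
  for (j in seq_along(k)) acc <- acc + k[j] * p[(j - 1) + seq_len(n), , drop = FALSE]
  # cols
  out <- matrix(0, n, m)
  for (j in seq_along(k)) out <- out + k[j] * acc[, (j - 1) + seq_len(m), drop = FALSE]
  out
}

#' Unsharp-mask sharpening
#'
#' `out = x + amount * (x - gaussian_blur(x, radius))`, clamped to `[0, 255]`.
#' Run before artifact thresholding so weak colony edges survive the rest of
#' the extraction chain.
#'
#' @param img `H x W x 3` array on the 0..255 scale.
#' @param radius Gaussian sigma in pixels.
#' @param amount dimensionless sharpening strength (0 = identity).
#' @return sharpened array, same shape.
#' @export
unsharp_mask <- function(img, radius, amount) {
  if (radius <= 0 || amount == 0) return(img)
  clamp(img + amount * (img - blur_gaussian(img, radius)), 0, 255)
}

#' Dilate a binary mask by a disc
#'
#' @param mask 0/1 matrix.
#' @param radius disc radius in pixels; 0 returns the mask unchanged.
#' @return 0/1 matrix of the same shape.
#' @export
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  side <- 2L * as.integer(radius) + 1L
  out <- EBImage::dilate(mask, EBImage::makeBrush(side, shape = "disc"))
  (out > 0) + 0
}

# Mean filter over a k x k window (k odd), reflected boundaries, via
# 2-D cumulative sums.
box_mean <- function(mat, k) {
  if (k <= 1) return(mat)
  f <- (k - 1L) %/% 2L
  p <- pad_reflect(mat, f)
  S <- apply(apply(p, 2, cumsum), 1, cumsum) # transposed cumsum matrix
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  n <- nrow(mat); m <- ncol(mat)
  i1 <- seq_len(n); i2 <- i1 + 2 * f
  j1 <- seq_len(m); j2 <- j1 + 2 * f
  (S[i2 + 1, j2 + 1] - S[i1, j2 + 1] - S[i2 + 1, j1] + S[i1, j1]) / (k * k)
}

#' Non-local-means denoising
#'
#' Removes speckle noise left behind by random-walk inpainting. Weights are
#' `exp(-d2 / strength^2)` where `d2` is the patchwise mean squared color
#' difference; `strength = 0` is the identity filter.
#'
#' @param img `H x W x 3` array, 0..255 scale.
#' @param strength filter strength `h` in intensity units.
#' @param patch odd patch size in pixels (side of the comparison window).
#' @param search odd search-window size in pixels.
#' @return denoised array clamped to `[0, 255]`.
#' @export
nlm_denoise <- function(img, strength, patch = 3L, search = 9L) {
  stopifnot(length(dim(img)) == 3L)
  if (strength <= 0) return(img)
  patch <- as.integer(patch); search <- as.integer(search)
  if (patch %% 2L == 0L) patch <- patch + 1L
  if (search %% 2L == 0L) search <- search + 1L
  t_off <- (search - 1L) %/% 2L
  n <- dim(img)[1]; m <- dim(img)[2]
  padc <- lapply(1:3, function(ch) pad_reflect(img[, , ch], t_off))
  ctr <- function(p) p[t_off + seq_len(n), t_off + seq_len(m), drop = FALSE]
  acc <- array(0, dim = dim(img))
  wsum <- matrix(0, n, m)
  h2 <- strength^2
  for (dy in -t_off:t_off) {
    for (dx in -t_off:t_off) {
      sh <- lapply(padc, function(p) {
        p[t_off + dy + seq_len(n), t_off + dx + seq_len(m), drop = FALSE]
      })
      d2 <- matrix(0, n, m)
      for (ch in 1:3) d2 <- d2 + (ctr(padc[[ch]]) - sh[[ch]])^2
      d2 <- box_mean(d2 / 3, patch)
      w <- exp(-d2 / h2)
      wsum <- wsum + w
      for (ch in 1:3) acc[, , ch] <- acc[, , ch] + w * sh[[ch]]
    }
  }
  for (ch in 1:3) acc[, , ch] <- acc[, , ch] / wsum
  clamp(acc, 0, 255)
}

flip_raster <- function(x, horizontal = FALSE, vertical = FALSE) {
  d <- dim(x)
  if (vertical) {
    x <- if (length(d) == 3L) x[rev(seq_len(d[1])), , , drop = FALSE] else x[rev(seq_len(d[1])), , drop = FALSE]
  }
  if (horizontal) {
    x <- if (length(d) == 3L) x[, rev(seq_len(d[2])), , drop = FALSE] else x[, rev(seq_len(d[2])), drop = FALSE]
  }
  x
}

#' Rotate a raster with bilinear interpolation
#'
#' Rotates about the image center. With `expand = TRUE` the output canvas
#' grows to hold the whole rotated image; pixels with no source are set to
#' `fill` (use `NA` to mark out-of-bounds regions, e.g. for valid-crop
#' searches, or 0 for transparent alpha).
#'
#' @param img `H x W` matrix or `H x W x C` array.
#' @param angle rotation angle in degrees, counter-clockwise.
#' @param expand grow the canvas to the rotated bounding box?
#' @param fill value for pixels outside the source.
#' @return rotated raster.
#' @export
rotate_bilinear <- function(img, angle, expand = TRUE, fill = NA_real_) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  nc <- if (length(d) == 3L) d[3] else 1L
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  if (expand) {
    H2 <- as.integer(ceiling(abs(h * ct) + abs(w * st) - 1e-9))
    W2 <- as.integer(ceiling(abs(w * ct) + abs(h * st) - 1e-9))
  } else {
    H2 <- h; W2 <- w
  }
  # output pixel-center offsets from output center
  oy <- seq_len(H2) - (H2 + 1) / 2
  ox <- seq_len(W2) - (W2 + 1) / 2
  YY <- matrix(oy, H2, W2)
  XX <- matrix(ox, H2, W2, byrow = TRUE)
  # inverse rotation back into source coordinates (row/col)
  sx <- ct * XX - st * YY + (w + 1) / 2
  sy <- st * XX + ct * YY + (h + 1) / 2
  valid <- which(sx >= 0.5 & sx <= w + 0.5 & sy >= 0.5 & sy <= h + 0.5)
  sx <- sx[valid]; sy <- sy[valid]
  x0 <- clamp(floor(sx), 1, w); y0 <- clamp(floor(sy), 1, h)
  x1 <- pmin(x0 + 1, w); y1 <- pmin(y0 + 1, h)
  fx <- clamp(sx - x0, 0, 1); fy <- clamp(sy - y0, 0, 1)
  # gather indices and bilinear weights, shared by all channels
  i00 <- (x0 - 1) * h + y0; i01 <- (x1 - 1) * h + y0
  i10 <- (x0 - 1) * h + y1; i11 <- (x1 - 1) * h + y1
  w00 <- (1 - fy) * (1 - fx); w01 <- (1 - fy) * fx
  w10 <- fy * (1 - fx); w11 <- fy * fx
  out <- array(fill, dim = c(H2, W2, nc))
  src <- if (length(d) == 3L) img else array(img, dim = c(h, w, 1L))
  np <- as.double(H2) * W2
  for (ch in seq_len(nc)) {
    plane <- src[, , ch]
    out[valid + (ch - 1) * np] <-
      w00 * plane[i00] + w01 * plane[i01] + w10 * plane[i10] + w11 * plane[i11]
  }
  if (length(d) == 3L) out else out[, , 1]
}
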