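#' Convert an 8-bit sRGB raster to CIELab
#'
#' Assumes sRGB primaries and the D65 white point. L* spans 0-100; a* and b*
#' are unbounded chroma axes (negative b* points toward blue, which is what
#' the dark-artifact detector thresholds on).
#'
#' @param img numeric array `H x W x 3` with values in `[0, 255]`.
#' @return numeric array `H x W x 3`: L*, a*, b*.
#' @export
srgb_to_lab <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  v <- img / 255
  # inverse sRGB companding
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  r <- lin[, , 1]; g <- lin[, , 2]; b <- lin[, , 3]
  # linear RGB -> XYZ (D65)
  x <- 0.4124564 * r + 0.3575761 * g + 0.1804375 * b
  y <- 0.2126729 * r + 0.7151522 * g + 0.0721750 * b
  z <- 0.0193339 * r + 0.1191920 * g + 0.9503041 * b
  # normalize by D65 white
  xn <- x / 0.95047; yn <- y; zn <- z / 1.08883
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xn); fy <- f(yn); fz <- f(zn)
  out <- array(0, dim = dim(img))
  out[, , 1] <- 116 * fy - 16
  out[, , 2] <- 500 * (fx - fy)
  out[, , 3] <- 200 * (fy - fz)
  out
}

# Relative luminance channel in [0, 1] used by the level-set segmenter.
luminance01 <- function(img) {
  (0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]) / 255
}
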