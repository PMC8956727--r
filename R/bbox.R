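# Bounding boxes are 0-based, half-open: a box (x, y, w, h) covers image
# columns [x, x + w) and rows [y, y + h), so a 1x1 box covers exactly one
# pixel. Boxes travel as rows of a data.frame with columns x, y, w, h.

#' Create a bounding-box record
#'
#' @param x,y 0-based column/row of the top-left corner.
#' @param w,h width and height in pixels, both > 0.
#' @return one-row `data.frame` with columns `x`, `y`, `w`, `h`.
#' @export
bbox <- function(x, y, w, h) {
  stopifnot(all(w > 0), all(h > 0))
  n <- max(length(x), length(y), length(w), length(h))
  stopifnot(all(c(length(x), length(y), length(w), length(h)) %in% c(1L, n)))
  data.frame(x = as.numeric(rep_len(x, n)), y = as.numeric(rep_len(y, n)),
             w = as.numeric(rep_len(w, n)), h = as.numeric(rep_len(h, n)))
}

bbox_area <- function(b) b$w * b$h

# Intersect a box with the image frame [0, W) x [0, H); may return w or h <= 0.
bbox_clip <- function(b, width, height) {
  x0 <- pmax(b$x, 0); y0 <- pmax(b$y, 0)
  x1 <- pmin(b$x + b$w, width); y1 <- pmin(b$y + b$h, height)
  data.frame(x = x0, y = y0, w = x1 - x0, h = y1 - y0)
}

# Rasterize one box into an existing H x W matrix (sets covered pixels to 1).
# Box coordinates are local to the matrix.
rasterize_box <- function(mask, b) {
  rows <- seq.int(floor(b$y) + 1L, length.out = max(0L, as.integer(round(b$h))))
  cols <- seq.int(floor(b$x) + 1L, length.out = max(0L, as.integer(round(b$w))))
  rows <- rows[rows >= 1 & rows <= nrow(mask)]
  cols <- cols[cols >= 1 & cols <= ncol(mask)]
  if (length(rows) && length(cols)) mask[rows, cols] <- 1
  mask
}

# Tight bounding box (half-open, 0-based) of the TRUE/nonzero pixels of a
# mask, or NULL if the mask is empty.
mask_tight_bbox <- function(mask) {
  nz <- which(mask > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(NULL)
  bbox(x = min(nz[, 2]) - 1, y = min(nz[, 1]) - 1,
       w = max(nz[, 2]) - min(nz[, 2]) + 1,
       h = max(nz[, 1]) - min(nz[, 1]) + 1)
}

#' The five default colony species labels
#'
#' Label set of the standard five-species agar-plate benchmark; category ids
#' in written datasets follow this (alphabetical) order.
#'
#' @return character vector of length 5.
#' @export
agar_species <- function() {
  c("B.subtilis", "C.albicans", "E.coli", "P.aeruginosa", "S.aureus")
}
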