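# Colonies whose bounding boxes overlap are extracted together as one
# cluster so that the mutual geometry of touching colonies is preserved in
# the pasted cutouts. The cluster relation is: boxes a, b are adjacent when
# intersection_area / min(area(a), area(b)) exceeds a threshold (default
# 0.01, strict). Connected components of that graph are the clusters.

#' Overlap fraction between two bounding boxes
#'
#' Intersection area divided by the smaller of the two box areas, so the
#' relation is symmetric and links two colonies whenever either loses more
#' than the threshold fraction of itself to the other.
#'
#' @param a,b one-row box data.frames from [bbox()].
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  ix <- min(a$x + a$w, b$x + b$w) - max(a$x, b$x)
  iy <- min(a$y + a$h, b$y + b$h) - max(a$y, b$y)
  inter <- max(0, ix) * max(0, iy)
  inter / min(bbox_area(a), bbox_area(b))
}

#' Build the colony adjacency matrix
#'
#' @param boxes data.frame of boxes (columns `x`, `y`, `w`, `h`), one row
#'   per colony.
#' @param threshold overlap fraction above which (strictly) two colonies
#'   are linked.
#' @return symmetric logical `N x N` matrix with a zero diagonal.
#' @export
build_adjacency <- function(boxes, threshold = 0.01) {
  n <- nrow(boxes)
  adj <- matrix(FALSE, n, n)
  if (n < 2L) return(adj)
  x0 <- boxes$x; y0 <- boxes$y
  x1 <- boxes$x + boxes$w; y1 <- boxes$y + boxes$h
  area <- boxes$w * boxes$h
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    ix <- pmax(0, pmin(x1[i], x1[j]) - pmax(x0[i], x0[j]))
    iy <- pmax(0, pmin(y1[i], y1[j]) - pmax(y0[i], y0[j]))
    frac <- (ix * iy) / pmin(area[i], area[j])
    hit <- j[frac > threshold]
    adj[i, hit] <- TRUE
    adj[hit, i] <- TRUE
  }
  adj
}

#' Extract connected colony clusters by breadth-first search
#'
#' @param adj adjacency matrix from [build_adjacency()].
#' @return list of integer vectors (1-based colony indices). Components are
#'   ordered by their smallest member; members are sorted ascending.
#'   Singleton clusters are permitted.
#' @export
connected_clusters <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(list())
  visited <- rep(FALSE, n)
  clusters <- list()
  for (start in seq_len(n)) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- which(adj[v, ] & !visited)
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    clusters[[length(clusters) + 1L]] <- sort(comp)
  }
  clusters
}
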