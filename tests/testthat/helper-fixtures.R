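# Shared, lazily built fixtures. Everything is generated in code under
# fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Small dishes for fast extraction-based tests.
small_fixture_cfg <- function(n_colonies = 4) {
  fixture_config(dish_diameter = 220, n_colonies = n_colonies)
}

# A cutout bank built from three small dishes (two species).
tiny_bank <- function() {
  memo("tiny_bank", {
    bank <- list()
    species <- c("E.coli", "S.aureus", "E.coli")
    for (s in 1:3) {
      fx <- make_annotated_dish(small_fixture_cfg(), seed = 100 + s,
                                species = species[s])
      for (co in extract_dish(fx$dish)) {
        bank[[co$species]] <- c(bank[[co$species]], list(co))
      }
    }
    bank
  })
}

small_empty <- function() {
  memo("small_empty",
       make_empty_dish(fixture_config(dish_diameter = 200), seed = 900))
}

# Random box set generator for graph tests.
random_boxes <- function(n, side = 200) {
  bbox(x = runif(n, 0, side - 20), y = runif(n, 0, side - 20),
       w = runif(n, 4, 20), h = runif(n, 4, 20))
}

# Independent union-find partition oracle.
uf_partition <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (adj[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(seq_len(n), roots), sort))
}
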