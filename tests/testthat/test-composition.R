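test_that("background crops have the right shape and are seed-reproducible", {
  empty <- small_empty()
  for (i in 1:5) {
    bg <- sample_background(empty, 96, seed = i)
    expect_equal(dim(bg), c(96, 96, 3))
    expect_false(anyNA(bg))
  }
  expect_identical(sample_background(empty, 96, seed = 42),
                   sample_background(empty, 96, seed = 42))
  expect_error(sample_background(empty, 5000, seed = 1), "too small")
})

test_that("zero-angle rotation is the identity (slice oracle)", {
  set.seed(2)
  img <- array(runif(40 * 30 * 3), dim = c(40, 30, 3))
  rot <- rotate_bilinear(img, 0, expand = TRUE, fill = NA_real_)
  expect_equal(dim(rot), dim(img))
  expect_equal(rot, img, tolerance = 1e-12)
})

test_that("colony counts follow the rounded exponential law", {
  set.seed(1)
  x <- sample_colony_count(100000, count_mean = 10)
  expect_true(all(x >= 0))
  expect_true(all(x == floor(x)))
  expect_lt(abs(mean(x) - 10), 0.15)
  # underlying continuous draws match the closed-form exponential CDF
  set.seed(1)
  raw <- sample_colony_count(100000, count_mean = 10, raw = TRUE)
  ks <- max(abs(ecdf(raw)(raw) - pexp(raw, rate = 0.1)))
  expect_lt(ks, 0.01)
  # vanishing mean: all draws round to zero
  set.seed(2)
  expect_true(all(sample_colony_count(1000, count_mean = 1e-6) == 0))
})

test_that("placement never overlaps and stays inside the patch", {
  bank <- tiny_bank()
  cutouts <- unlist(bank, recursive = FALSE)
  S <- 300L
  occupancy <- matrix(0, S, S)
  footprints <- list()
  set.seed(33)
  placed <- 0
  for (i in 1:60) {
    co <- cutouts[[(i - 1) %% length(cutouts) + 1]]
    pl <- try_place(occupancy, co, max_attempts = 30)
    if (is.null(pl)) next
    placed <- placed + 1
    h <- nrow(pl$cutout$alpha); w <- ncol(pl$cutout$alpha)
    expect_true(pl$row >= 1 && pl$col >= 1)
    expect_true(pl$row + h <= S - 1 && pl$col + w <= S - 1)
    fp_full <- matrix(0, S, S)
    fp_full[pl$row + seq_len(h), pl$col + seq_len(w)] <- (pl$cutout$alpha > 0)
    for (prev in footprints) expect_equal(sum(fp_full * prev), 0)
    footprints[[length(footprints) + 1]] <- fp_full
    prow <- pl$row:(pl$row + h + 1); pcol <- pl$col:(pl$col + w + 1)
    occupancy[prow, pcol] <- pmax(occupancy[prow, pcol], pl$footprint)
  }
  expect_gt(placed, 10)
  # a fully occupied patch fails after exhausting the attempt budget
  expect_null(try_place(matrix(1, S, S), cutouts[[1]], max_attempts = 5))
})

test_that("alpha-over blending matches the convex-combination oracle", {
  set.seed(9)
  P <- 140L
  patch <- round(array(runif(P * P * 3, 0, 255), dim = c(P, P, 3)))
  co <- tiny_bank()[[1]][[1]]
  tc <- list(rgb = co$rgb, alpha = co$alpha, masks = co$masks)
  pl <- list(cutout = tc, row = 3L, col = 4L)
  h <- nrow(tc$alpha); w <- ncol(tc$alpha)
  expect_true(h + 4 <= P && w + 4 <= P)
  out <- blend_patch(patch, pl)
  # oracle: per-pixel convex combination
  for (ch in 1:3) {
    region <- patch[pl$row + seq_len(h), pl$col + seq_len(w), ch]
    want <- round(tc$alpha / 255 * tc$rgb[, , ch] + (1 - tc$alpha / 255) * region)
    expect_equal(out[pl$row + seq_len(h), pl$col + seq_len(w), ch], want)
  }
  # opaque and transparent limits
  tc255 <- tc; tc255$alpha <- matrix(255, h, w)
  out255 <- blend_patch(patch, list(cutout = tc255, row = 3L, col = 4L))
  expect_equal(out255[3 + seq_len(h), 4 + seq_len(w), 1], round(tc$rgb[, , 1]))
  tc0 <- tc; tc0$alpha <- matrix(0, h, w)
  expect_equal(blend_patch(patch, list(cutout = tc0, row = 3L, col = 4L)), patch)
  # pixels outside the footprint are untouched
  expect_equal(out[1, , ], patch[1, , ])
})

test_that("generated patches have consistent annotations", {
  bank <- tiny_bank()
  cfg <- composition_config(patch_size = 160L, count_mean = 4)
  for (seed in c(5, 6, 7)) {
    rec <- generate_patch(bank, list(small_empty()), cfg, seed = seed)
    expect_equal(dim(rec$image)[1:2], c(160, 160))
    expect_equal(nrow(rec$annotations), length(rec$masks))
    # one species per patch
    if (nrow(rec$annotations) > 0) {
      expect_length(unique(rec$annotations$species), 1)
    }
    # every stored bbox is the tight box of its mask
    for (k in seq_along(rec$masks)) {
      tb <- petrigen:::mask_tight_bbox(rec$masks[[k]])
      a <- rec$annotations[k, ]
      expect_equal(c(tb$x, tb$y, tb$w, tb$h), c(a$x, a$y, a$w, a$h))
    }
  }
  # vanishing count mean: background-only patch
  rec0 <- generate_patch(bank, list(small_empty()),
                         composition_config(patch_size = 96L, count_mean = 1e-6),
                         seed = 3)
  expect_equal(nrow(rec0$annotations), 0)
  expect_length(rec0$masks, 0)
})

test_that("dataset generation is deterministic and patches are independently reproducible", {
  bank <- tiny_bank()
  cfg <- composition_config(patch_size = 128L, count_mean = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(bank, list(small_empty()), cfg, n_patches = 4, seed = 17,
                   out_dir = d1)
  generate_dataset(bank, list(small_empty()), cfg, n_patches = 4, seed = 17,
                   out_dir = d2)
  for (f in c("manifest.json", "annotations.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 10^7),
                     readBin(file.path(d2, f), "raw", 10^7))
  }
  # patch 3 regenerated alone from (seed, index) matches the dataset record
  rec3 <- generate_patch(bank, list(small_empty()), cfg,
                         seed = derive_seed(17, 3))
  back <- read_dataset(d1)
  expect_equal(back[[3]]$annotations[, c("x", "y", "w", "h", "species")],
               rec3$annotations[, c("x", "y", "w", "h", "species")])
  expect_equal(back[[3]]$image, rec3$image)
})
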