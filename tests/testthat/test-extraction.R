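flat_dish <- function(side = 60, value = c(120, 110, 100)) {
  img <- array(0, dim = c(side, side, 3))
  for (ch in 1:3) img[, , ch] <- value[ch]
  img
}

test_that("cut_cluster rasterizes the box union exactly", {
  dish <- petrigen:::new_annotated_dish(
    flat_dish(60),
    data.frame(instance_id = 1:3,
               x = c(5, 5, 11), y = c(5, 30, 18), w = c(10, 10, 10),
               h = c(10, 10, 14), species = "E.coli"),
    "t")
  # single 10x10 box, margin 0: fragment exactly the box, m_bx all ones
  one <- cut_cluster(dish, 1L, margin = 0)
  expect_equal(dim(one$rgb)[1:2], c(10, 10))
  expect_true(all(one$m_bx == 1))

  # boxes 1 and 2 are disjoint in y but linked through box 3:
  # m_bx must be zero in the uncovered gap
  cl <- cut_cluster(dish, 1:3, margin = 0)
  # pixel at global (row 16, col 6) is covered by no box (y gap at x=5)
  expect_equal(cl$m_bx[16 - cl$offset[1], 6 - cl$offset[2]], 0)

  # sum(m_bx) equals union area from independent per-box rasterization
  ref <- matrix(0, dim(dish$image)[1], dim(dish$image)[2])
  for (i in 1:3) ref <- pmax(ref, petrigen:::rasterize_box(ref * 0, dish$annotations[i, ]))
  expect_equal(sum(cl$m_bx), sum(ref))
  # local boxes re-expressed in fragment coordinates
  expect_equal(cl$boxes$x, dish$annotations$x - cl$offset[2])
})

test_that("dark-artifact removal inpaints only masked pixels from valid donors", {
  cfg <- extraction_config(dark_dilate_radius = 1, rng_seed = 5)
  # artifact-free fragment: identity, empty mask
  frag <- flat_dish(30, c(150, 140, 130))
  res <- remove_dark_artifacts(frag, cfg)
  expect_equal(sum(res$m_d), 0)
  expect_identical(res$rgb, frag)

  # single dark pixel surrounded by uniform color: must take that color
  frag2 <- flat_dish(21, c(150, 140, 130))
  frag2[11, 11, ] <- c(5, 5, 5)
  res2 <- remove_dark_artifacts(frag2, extraction_config(dark_dilate_radius = 0,
                                                         rng_seed = 2))
  expect_equal(res2$rgb[11, 11, ], c(150, 140, 130))

  # multi-pixel artifact: every replaced value is a member of the valid
  # multiset; unmasked pixels are bit-exact
  frag3 <- flat_dish(40, c(160, 150, 140)) +
    array(round(runif(40 * 40 * 3, -10, 10)), dim = c(40, 40, 3))
  frag3[15:20, 10:12, ] <- 8 # dark block
  cfg3 <- extraction_config(dark_dilate_radius = 1, rng_seed = 9)
  res3 <- remove_dark_artifacts(frag3, cfg3)
  valid_vals <- apply(frag3, 3, function(p) p[res3$m_d == 0])
  for (idx in which(res3$m_d > 0)) {
    rc <- arrayInd(idx, dim(res3$m_d))
    v <- res3$rgb[rc[1], rc[2], ]
    hit <- which(valid_vals[, 1] == v[1] & valid_vals[, 2] == v[2] &
                   valid_vals[, 3] == v[3])
    expect_gt(length(hit), 0)
  }
  expect_identical(res3$rgb[res3$m_d == 0], frag3[res3$m_d == 0])

  # reproducible under the same seed
  res3b <- remove_dark_artifacts(frag3, cfg3)
  expect_identical(res3$rgb, res3b$rgb)

  # fully dark fragment: no donors
  expect_error(remove_dark_artifacts(flat_dish(10, c(3, 3, 3)), cfg),
               "no valid pixels")
})

test_that("non-local means denoises speckle and respects its null settings", {
  const <- flat_dish(30, c(100, 100, 100))
  expect_equal(nlm_denoise(const, strength = 10), const)
  # salt-and-pepper on a uniform image: MAD to the clean image decreases
  set.seed(4)
  noisy <- const
  idx <- sample(30 * 30, 9) # 1% density
  for (i in idx) {
    rc <- arrayInd(i, c(30, 30))
    noisy[rc[1], rc[2], ] <- if (runif(1) < 0.5) 0 else 255
  }
  den <- nlm_denoise(noisy, strength = 12, patch = 3)
  expect_lt(mean(abs(den - const)), mean(abs(noisy - const)))
  # zero strength is the identity
  expect_true(max(abs(nlm_denoise(noisy, strength = 0) - noisy)) <= 1)
})

test_that("Chan-Vese recovers a synthetic disk and degrades gracefully", {
  n <- 80
  yy <- matrix(1:n, n, n); xx <- t(yy)
  disk <- sqrt((yy - 40)^2 + (xx - 40)^2) <= 16
  img <- flat_dish(n, c(50, 50, 50))
  for (ch in 1:3) { p <- img[, , ch]; p[disk] <- 200; img[, , ch] <- p }
  cfg <- extraction_config(seg_dilate_radius = 0)
  m_s <- segment_chan_vese(img, cfg)
  iou <- sum(m_s > 0 & disk) / sum(m_s > 0 | disk)
  expect_gte(iou, 0.95)

  # constant fragment: empty mask with a warning
  expect_warning(m0 <- segment_chan_vese(flat_dish(20), cfg), "constant")
  expect_equal(sum(m0), 0)

  # dilation monotonicity
  cfg2 <- extraction_config(seg_dilate_radius = 2)
  m_d <- segment_chan_vese(img, cfg2)
  expect_true(all(m_d[m_s > 0] > 0))
  expect_gt(sum(m_d), sum(m_s))
})

test_that("blending mask is the normalized CIELab background distance", {
  # two-color fragment: A outside m_s, B inside -> 0 on A, 255 on B
  frag <- flat_dish(20, c(90, 90, 90))
  m_s <- matrix(0, 20, 20); m_s[8:12, 8:12] <- 1
  for (ch in 1:3) { p <- frag[, , ch]; p[m_s > 0] <- c(220, 40, 40)[ch]; frag[, , ch] <- p }
  m_b <- blending_mask(frag, m_s)
  expect_true(all(m_b[m_s == 0] == 0)) # pixels equal to the background mean
  expect_true(all(m_b[m_s > 0] == 255)) # the unique maximal distance
  # all-foreground mask has no background sample
  expect_error(blending_mask(frag, matrix(1, 20, 20)), "no background")
})

test_that("alpha is the Hadamard product of the three masks", {
  set.seed(8)
  m_bx <- matrix(rbinom(100, 1, 0.6), 10)
  m_s <- matrix(rbinom(100, 1, 0.6), 10)
  m_b <- matrix(sample(0:255, 100, TRUE), 10)
  alpha <- compose_alpha(m_bx, m_s, m_b)
  # independent per-pixel triple-product oracle
  for (i in 1:10) for (j in 1:10) {
    expect_equal(alpha[i, j], m_bx[i, j] * m_s[i, j] * m_b[i, j])
  }
  expect_true(all(compose_alpha(m_bx, matrix(0, 10, 10), m_b) == 0))
  expect_true(all(compose_alpha(matrix(1, 10, 10), matrix(1, 10, 10),
                                matrix(255, 10, 10)) == 255))
  expect_error(compose_alpha(m_bx, m_s, matrix(0, 5, 5)), "shapes")
})

test_that("extract_cluster returns consistent cutouts on fixture dishes", {
  fx <- make_annotated_dish(small_fixture_cfg(n_colonies = 3), seed = 55,
                            species = "C.albicans")
  adj <- build_adjacency(fx$dish$annotations)
  clusters <- connected_clusters(adj)
  co <- extract_cluster(fx$dish, clusters[[1]])
  expect_s3_class(co, "cluster_cutout")
  # alpha is exactly 0 outside the box union
  expect_true(all(co$alpha[co$m_bx == 0] == 0))
  # alpha never exceeds the blending mask
  expect_true(all(co$alpha <= co$m_b))
  # cardinality: one box and one mask per member colony
  expect_equal(nrow(co$boxes), length(clusters[[1]]))
  expect_length(co$masks, length(clusters[[1]]))

  # single-colony dish: recovered mask close to ground truth
  fx1 <- make_annotated_dish(small_fixture_cfg(n_colonies = 1), seed = 77,
                             species = "E.coli")
  co1 <- extract_dish(fx1$dish)[[1]]
  tm <- fx1$truth_masks[[1]]
  H <- dim(fx1$dish$image)[1]; W <- dim(fx1$dish$image)[2]
  gp <- matrix(0, H, W)
  gp[co1$offset[1] + seq_len(nrow(co1$alpha)),
     co1$offset[2] + seq_len(ncol(co1$alpha))] <- co1$masks[[1]]
  gt <- matrix(0, H, W)
  gt[tm$offset[1] + seq_len(nrow(tm$mask)),
     tm$offset[2] + seq_len(ncol(tm$mask))] <- tm$mask
  expect_gte(sum(gp * gt) / sum((gp + gt) > 0), 0.8)
})
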