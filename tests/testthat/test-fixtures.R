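test_that("empty dishes look like dishes and are reproducible", {
  cfg <- fixture_config(dish_diameter = 180)
  d1 <- make_empty_dish(cfg, seed = 5)
  d2 <- make_empty_dish(cfg, seed = 5)
  expect_equal(nrow(d1$annotations), 0)
  expect_identical(d1$image, d2$image)
  expect_false(identical(d1$image, make_empty_dish(cfg, seed = 6)$image))
  # brighter inside the dish than outside
  side <- dim(d1$image)[1]
  yy <- matrix(seq_len(side) - (side + 1) / 2, side, side)
  r <- sqrt(yy^2 + t(yy)^2)
  lum <- petrigen:::luminance01(d1$image)
  expect_gt(mean(lum[r < 80]), mean(lum[r > 100]))
})

test_that("annotated dishes carry exact counts, boxes and in-dish masks", {
  cfg <- fixture_config(dish_diameter = 220, n_colonies = 5)
  fx <- make_annotated_dish(cfg, seed = 9, species = "B.subtilis")
  expect_equal(nrow(fx$dish$annotations), 5)
  expect_length(fx$truth_masks, 5)
  expect_true(all(fx$dish$annotations$species == "B.subtilis"))
  side <- dim(fx$dish$image)[1]
  R <- cfg$dish_diameter / 2
  for (k in 1:5) {
    tm <- fx$truth_masks[[k]]
    expect_gt(sum(tm$mask), 0)
    # every mask pixel lies inside the dish disk
    nz <- which(tm$mask > 0, arr.ind = TRUE)
    gy <- nz[, 1] + tm$offset[1]; gx <- nz[, 2] + tm$offset[2]
    expect_true(all(sqrt((gy - (side + 1) / 2)^2 + (gx - (side + 1) / 2)^2) <= R))
    # the stored box is the tight bbox of the mask (offset into dish coords)
    tb <- petrigen:::mask_tight_bbox(tm$mask)
    a <- fx$dish$annotations[k, ]
    expect_equal(a$x, tb$x + tm$offset[2])
    expect_equal(a$y, tb$y + tm$offset[1])
    expect_equal(c(a$w, a$h), c(tb$w, tb$h))
  }
})

test_that("forced overlaps produce multi-colony clusters", {
  cfg <- fixture_config(dish_diameter = 220, n_colonies = 2,
                        overlap_probability = 1)
  fx <- make_annotated_dish(cfg, seed = 31, species = "E.coli")
  boxes <- fx$dish$annotations
  expect_gt(overlap_fraction(boxes[1, ], boxes[2, ]), 0.01)
  clusters <- connected_clusters(build_adjacency(boxes))
  expect_length(clusters, 1)
  expect_equal(clusters[[1]], 1:2)
})

test_that("overfull dishes are rejected with advice", {
  cfg <- fixture_config(dish_diameter = 150, n_colonies = 200,
                        overlap_probability = 0)
  expect_error(make_annotated_dish(cfg, seed = 1), "smaller|reduce")
})

test_that("a written fixture set reads back through the standard reader", {
  dir <- withr::local_tempdir()
  write_fixture_set(dir, n_dishes = 2, n_empty = 1,
                    cfg = fixture_config(dish_diameter = 160, n_colonies = 3),
                    seed = 4)
  jsons <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  expect_length(jsons, 3)
  dishes <- lapply(jsons, function(ap) {
    read_annotated_dish(sub("json$", "png", ap), ap)
  })
  n_ann <- vapply(dishes, function(d) nrow(d$annotations), numeric(1))
  expect_setequal(n_ann, c(3, 3, 0))
})
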