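test_that("overlap_fraction matches interval arithmetic and is symmetric", {
  a <- bbox(0, 0, 10, 10)
  b <- bbox(5, 5, 10, 10)
  expect_equal(overlap_fraction(a, b), 0.25)
  expect_equal(overlap_fraction(bbox(0, 0, 5, 5), bbox(50, 50, 5, 5)), 0)
  expect_equal(overlap_fraction(a, a), 1)
  set.seed(41)
  for (i in 1:50) {
    bx <- random_boxes(2)
    expect_equal(overlap_fraction(bx[1, ], bx[2, ]),
                 overlap_fraction(bx[2, ], bx[1, ]))
  }
})

test_that("adjacency uses a strict threshold and matches brute force", {
  # two equal 100x100 boxes sharing exactly 1% of their area: no edge
  a <- bbox(0, 0, 100, 100)
  b <- bbox(99, 0, 100, 100) # intersection 1 x 100 = 100 px = 0.01 of area
  expect_equal(overlap_fraction(a, b), 0.01)
  expect_false(build_adjacency(rbind(a, b))[1, 2])
  # nudge one pixel closer -> fraction 0.02 > 0.01 -> edge
  b2 <- bbox(98, 0, 100, 100)
  expect_true(build_adjacency(rbind(a, b2))[1, 2])

  # isolated boxes
  iso <- bbox(x = seq(0, 90, 30), y = 0, w = 10, h = 10)
  expect_false(any(build_adjacency(iso)))

  # 50 random boxes vs an independent pairwise recomputation
  set.seed(42)
  boxes <- random_boxes(50, side = 120)
  adj <- build_adjacency(boxes, threshold = 0.01)
  expect_true(isSymmetric(adj))
  expect_false(any(diag(adj)))
  for (i in 1:49) for (j in (i + 1):50) {
    ix <- max(0, min(boxes$x[i] + boxes$w[i], boxes$x[j] + boxes$w[j]) -
                max(boxes$x[i], boxes$x[j]))
    iy <- max(0, min(boxes$y[i] + boxes$h[i], boxes$y[j] + boxes$h[j]) -
                max(boxes$y[i], boxes$y[j]))
    frac <- ix * iy / min(boxes$w[i] * boxes$h[i], boxes$w[j] * boxes$h[j])
    expect_identical(adj[i, j], frac > 0.01)
  }
})

test_that("BFS clusters equal a union-find oracle and partition the nodes", {
  # chain A-B, B-C, no C-A: one cluster (transitive closure)
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- TRUE
  adj[2, 3] <- adj[3, 2] <- TRUE
  expect_identical(connected_clusters(adj), list(1:3))

  # empty graph on 4 nodes: 4 singletons
  expect_identical(connected_clusters(matrix(FALSE, 4, 4)),
                   list(1L, 2L, 3L, 4L))

  set.seed(7)
  for (trial in 1:100) {
    n <- sample(2:25, 1)
    adj <- matrix(runif(n * n) < 0.08, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    got <- connected_clusters(adj)
    want <- uf_partition(adj)
    # same partition regardless of component ordering
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
    expect_equal(sum(lengths(got)), n)
    # deterministic ordering contract
    expect_equal(order(vapply(got, min, numeric(1))), seq_along(got))
  }
})

test_that("cluster membership is invariant under box permutation", {
  set.seed(11)
  boxes <- random_boxes(30, side = 80)
  part1 <- connected_clusters(build_adjacency(boxes))
  perm <- sample(30)
  part2 <- connected_clusters(build_adjacency(boxes[perm, ]))
  # map permuted indices back and compare as sets of sets
  back <- lapply(part2, function(cl) sort(perm[cl]))
  expect_setequal(lapply(part1, paste, collapse = ","),
                  lapply(back, paste, collapse = ","))
})
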