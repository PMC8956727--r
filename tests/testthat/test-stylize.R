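test_that("gram matches its closed forms and a brute-force loop", {
  expect_equal(gram(array(0, dim = c(4, 5, 3))), matrix(0, 3, 3))
  # constant map, every channel value v: all entries v^2 / C
  v <- 2
  expect_equal(gram(array(v, dim = c(4, 4, 3))), matrix(v^2 / 3, 3, 3))
  # random tensor vs double loop
  set.seed(6)
  f <- array(rnorm(3 * 4 * 4), dim = c(4, 4, 3))
  G <- gram(f)
  want <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    want[i, j] <- sum(f[, , i] * f[, , j]) / (3 * 4 * 4)
  }
  expect_equal(G, want)
  expect_true(isSymmetric(G))
  expect_true(all(eigen(G, only.values = TRUE)$values > -1e-12))
})

test_that("the style/content loss vanishes at its two anchors and mixes linearly", {
  set.seed(10)
  y_c <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  y_s <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  layers <- c("block1", "block2")
  cfg0 <- style_config(lambda_weight = 0, feature_layers = layers,
                       tile_size = 16, patches_per_tile = 1)
  expect_equal(style_content_loss(y_c, y_c, y_s, cfg0), 0)
  cfg1 <- style_config(lambda_weight = 1, feature_layers = layers,
                       tile_size = 16, patches_per_tile = 1)
  expect_equal(style_content_loss(y_s, y_c, y_s, cfg1), 0)
  # lambda = 0.5: arithmetic mean of the two separately evaluated terms
  y <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  half <- style_config(lambda_weight = 0.5, feature_layers = layers,
                       tile_size = 16, patches_per_tile = 1)
  c_term <- style_content_loss(y, y_c, y, half) * 2 # style term 0 here
  s_term <- style_content_loss(y, y, y_s, half) * 2 # content term 0 here
  expect_equal(style_content_loss(y, y_c, y_s, half), (c_term + s_term) / 2)
  expect_error(style_content_loss(y, y_c, y_s,
                                  style_config(feature_layers = character(0),
                                               tile_size = 16,
                                               patches_per_tile = 1)),
               "feature_layers")
})

test_that("the loss gradient matches central finite differences", {
  set.seed(5)
  cfg <- style_config(lambda_weight = 0.3, feature_layers = c("block1", "block2"),
                      tile_size = 2, patches_per_tile = 1)
  y <- array(runif(8, 0.2, 0.8), dim = c(2, 2, 2))
  y_c <- array(runif(8, 0.2, 0.8), dim = c(2, 2, 2))
  y_s <- array(runif(8, 0.2, 0.8), dim = c(2, 2, 2))
  lg <- petrigen:::style_content_loss_grad(y, y_c, y_s, cfg)
  h <- 1e-5
  num <- array(0, dim(y))
  for (i in seq_along(y)) {
    yp <- y; yp[i] <- yp[i] + h
    ym <- y; ym[i] <- ym[i] - h
    num[i] <- (style_content_loss(yp, y_c, y_s, cfg) -
                 style_content_loss(ym, y_c, y_s, cfg)) / (2 * h)
  }
  expect_lt(max(abs(num - lg$grad)) / max(abs(num)), 1e-3)
})

test_that("generators have the contracted shapes, sizes and gradients", {
  set.seed(3)
  for (arch in c("highres", "light")) {
    for (S in c(64L, 128L)) {
      gen <- build_generator(arch, S, seed = 2)
      x <- array(runif(S * S * 3), dim = c(S, S, 3))
      fw <- petrigen:::generator_forward(gen, x)
      expect_equal(dim(fw$y), dim(x))
      # finite gradients for a random loss direction
      g <- petrigen:::generator_backward(gen, fw$cache,
                                         array(rnorm(length(x)), dim = dim(x)))
      expect_true(all(vapply(g, function(p) all(is.finite(p$dW)) && all(is.finite(p$db)),
                             logical(1))))
    }
  }
  expect_lt(generator_n_params(build_generator("light", 64)),
            generator_n_params(build_generator("highres", 64)))
  expect_error(build_generator("light", 66), "stride")
})

test_that("one-shot training reduces the loss and respects zero iterations", {
  set.seed(1)
  ct <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  st <- array(runif(64 * 64 * 3)^2, dim = c(64, 64, 3))
  cfg <- style_config(lambda_weight = 0.05, iterations = 30, tile_size = 64,
                      patches_per_tile = 1, arch = "light")
  fit <- train_stylizer(ct, st, cfg, seed = 2)
  expect_length(fit$loss_trace, 30)
  expect_lt(fit$loss_trace[30], fit$loss_trace[1])
  expect_true(all(is.finite(fit$loss_trace)))
  # zero iterations: returned weights equal the initialization
  cfg0 <- style_config(lambda_weight = 0.05, iterations = 0, tile_size = 64,
                       patches_per_tile = 1, arch = "light")
  init <- build_generator("light", 64, seed = 2)
  fit0 <- train_stylizer(ct, st, cfg0, init_weights = init)
  expect_identical(fit0$weights$params, init$params)
})

test_that("warm starts begin at or below the cold-start loss", {
  wins <- 0
  for (s in 1:5) {
    set.seed(s)
    ct <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
    st <- array(runif(32 * 32 * 3)^2, dim = c(32, 32, 3))
    cfg <- style_config(lambda_weight = 0.05, iterations = 15, tile_size = 32,
                        patches_per_tile = 1, arch = "light")
    first <- train_stylizer(ct, st, cfg, seed = s)
    # a second tile from the same scene family
    set.seed(s + 50)
    ct2 <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
    warm <- train_stylizer(ct2, st, cfg, init_weights = first$weights)
    cold <- train_stylizer(ct2, st, cfg, seed = s + 99)
    if (warm$loss_trace[1] <= cold$loss_trace[1]) wins <- wins + 1
  }
  expect_gte(wins, 4) # >= 80% of trials
})

test_that("lambda monotonically pulls outputs toward the style statistics", {
  style_dist <- function(y, ys, cfg) {
    ext <- petrigen:::build_feature_extractor(3)
    fy <- petrigen:::extractor_forward(ext, y, cfg$feature_layers)$features
    fs <- petrigen:::extractor_forward(ext, ys, cfg$feature_layers)$features
    sum(vapply(cfg$feature_layers,
               function(nm) sum((gram(fy[[nm]]) - gram(fs[[nm]]))^2), numeric(1)))
  }
  d_semi <- d_full <- numeric(5)
  for (s in 1:5) {
    set.seed(s)
    ct <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
    st <- array(runif(32 * 32 * 3)^2, dim = c(32, 32, 3))
    for (lam in c(0.02, 0.05)) {
      cfg <- style_config(lambda_weight = lam, iterations = 40, tile_size = 32,
                          patches_per_tile = 1, arch = "light")
      fit <- train_stylizer(ct, st, cfg, seed = s + 100)
      if (lam == 0.02) d_semi[s] <- style_dist(fit$y, st, cfg)
      else d_full[s] <- style_dist(fit$y, st, cfg)
    }
  }
  expect_lte(mean(d_full), mean(d_semi))
})

test_that("tile assembly round-trips and stylization preserves annotations", {
  bank <- tiny_bank()
  cfg <- composition_config(patch_size = 64L, count_mean = 2)
  records <- lapply(1:4, function(i) {
    generate_patch(bank, list(small_empty()), cfg, seed = 700 + i)
  })
  style <- small_empty()$image[1:64, 1:64, ]
  # identity stylizer: zero iterations with the identity-initialized
  # residual generator leave the patches unchanged through assemble/split
  scfg0 <- style_config(lambda_weight = 0.05, iterations = 0, tile_size = 128,
                        patches_per_tile = 4, arch = "light")
  out0 <- stylize_batch(records, style, scfg0, seed = 4)
  for (i in 1:4) {
    expect_equal(out0$records[[i]]$image, records[[i]]$image)
  }
  # a real (short) stylization changes pixels but never annotations/masks
  scfg <- style_config(lambda_weight = 0.05, iterations = 3, tile_size = 128,
                       patches_per_tile = 4, arch = "light")
  out <- stylize_batch(records, style, scfg, seed = 4, style_id = "s7")
  for (i in 1:4) {
    expect_identical(out$records[[i]]$annotations, records[[i]]$annotations)
    expect_identical(out$records[[i]]$masks, records[[i]]$masks)
    expect_equal(dim(out$records[[i]]$image), dim(records[[i]]$image))
    expect_equal(out$records[[i]]$provenance$style, "s7")
  }
  # geometry contracts are enforced
  expect_error(stylize_batch(records[1:3], style, scfg), "expected 4")
  bad <- style_config(lambda_weight = 0.05, iterations = 0, tile_size = 999,
                      patches_per_tile = 4, arch = "light")
  expect_error(stylize_batch(records, style, bad), "tile_size")
})
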