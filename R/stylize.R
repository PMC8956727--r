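# One-shot neural style transfer. A small image-generation network is
# trained per (content tile, style image) pair by plain SGD to minimize
#
#   L(y, y_c, y_s) = (1 - lambda) * sum_l || G_l(y) - G_l(y_c) ||_F^2
#                  +      lambda  * sum_l || G_l(y) - G_l(y_s) ||_F^2
#
# where G_l are Gram matrices of frozen extractor features. The squared
# Frobenius norm is the standard Gram-loss convention; it is also what
# makes gradient descent from the identity-initialized generator possible
# (with unsquared norms and lambda < 1/2 the content optimum y = y_c is a
# local minimum of L, because the content term grows linearly in any
# direction while the style term falls at most linearly with a smaller
# weight). lambda mixes content fidelity against style: 0.02 gives a
# semi-stylized look, 0.05 a fully-stylized one. Both terms use Gram
# statistics; a raw feature-matching content term is available behind
# `content_gram = FALSE` (the common perceptual-loss convention).

#' Style-transfer configuration
#'
#' @param lambda_weight style weight in `[0, 1]`; 0.02 = semi-stylized,
#'   0.05 = fully-stylized. Values above 0.05 tend to wash out
#'   class-relevant colony appearance and trigger a warning downstream.
#' @param feature_layers extractor taps entering the loss.
#' @param iterations SGD steps.
#' @param learning_rate SGD learning rate.
#' @param tile_size side of the stylization tile (4 patches per tile by
#'   default, so 1024 for 512-px patches). Must equal
#'   `patch_size * sqrt(patches_per_tile)`.
#' @param patches_per_tile patches stylized jointly per tile.
#' @param warm_start reuse the previous tile's generator weights?
#' @param arch generator architecture, see [build_generator()].
#' @param content_gram if `FALSE`, the content term compares raw feature
#'   maps instead of their Gram matrices.
#' @return list of class `style_config`.
#' @export
style_config <- function(lambda_weight = 0.05,
                         feature_layers = paste0("block", 1:5),
                         iterations = 200L, learning_rate = 1e-4,
                         tile_size = 1024L, patches_per_tile = 4L,
                         warm_start = TRUE, arch = "highres",
                         content_gram = TRUE) {
  stopifnot_scalar_number(lambda_weight, "lambda_weight", 0, 1)
  stopifnot(length(feature_layers) >= 1, iterations >= 0, learning_rate > 0)
  k <- sqrt(patches_per_tile)
  if (k != floor(k)) stop("patches_per_tile must be a perfect square", call. = FALSE)
  structure(list(lambda_weight = lambda_weight,
                 feature_layers = feature_layers,
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate,
                 tile_size = as.integer(tile_size),
                 patches_per_tile = as.integer(patches_per_tile),
                 warm_start = warm_start, arch = arch,
                 content_gram = content_gram),
            class = "style_config")
}

#' Gram matrix of a feature map
#'
#' `G = F F^T / (C H W)` where `F` is the `C x (H W)` unrolling of the
#' feature tensor; symmetric and positive semi-definite, independent of the
#' spatial size of the map.
#'
#' @param features `H x W x C` array.
#' @return `C x C` matrix.
#' @export
gram <- function(features) {
  d <- dim(features)
  stopifnot(length(d) == 3L, d[1] * d[2] >= 1)
  f <- t(as_mat(features)) # C x (H W)
  tcrossprod(f) / (d[3] * d[1] * d[2])
}

# d/dF of || G(F) - G0 ||_F^2 pushed back to the feature tensor.
gram_norm_backward <- function(features, G, G0) {
  d <- dim(features)
  M <- 2 * (G - G0)
  f <- t(as_mat(features))
  dF <- (M + t(M)) %*% f / (d[3] * d[1] * d[2])
  array(t(dF), dim = d)
}

# Loss and gradient w.r.t. y. targets_c / targets_s are per-layer Gram
# matrices (or raw features for the non-Gram content term).
style_loss_grad <- function(y, targets_c, targets_s, cfg, ext,
                            want_grad = TRUE) {
  fw <- extractor_forward(ext, y, cfg$feature_layers)
  lam <- cfg$lambda_weight
  loss <- 0
  dfeats <- list()
  for (nm in cfg$feature_layers) {
    f <- fw$features[[nm]]
    G <- gram(f)
    df <- array(0, dim = dim(f))
    # content term (squared Frobenius Gram distance)
    if (cfg$content_gram) {
      dc <- sum((G - targets_c[[nm]])^2)
      loss <- loss + (1 - lam) * dc
      if (want_grad && dc > 0) {
        df <- df + (1 - lam) * gram_norm_backward(f, G, targets_c[[nm]])
      }
    } else {
      diff <- f - targets_c[[nm]]
      loss <- loss + (1 - lam) * sum(diff^2)
      if (want_grad) df <- df + (1 - lam) * 2 * diff
    }
    # style term (always Gram, squared Frobenius)
    ds <- sum((G - targets_s[[nm]])^2)
    loss <- loss + lam * ds
    if (want_grad && ds > 0) {
      df <- df + lam * gram_norm_backward(f, G, targets_s[[nm]])
    }
    dfeats[[nm]] <- df
  }
  grad <- if (want_grad) extractor_backward(ext, fw, dfeats) else NULL
  list(loss = loss, grad = grad)
}

style_targets <- function(img, cfg, ext, use_gram) {
  fw <- extractor_forward(ext, img, cfg$feature_layers)
  lapply(fw$features[cfg$feature_layers],
         function(f) if (use_gram) gram(f) else f)
}

#' Style/content loss between an output and its content and style images
#'
#' @param y output image, `H x W x 3` in `[0, 1]`.
#' @param y_c content image, same geometry as `y`.
#' @param y_s style image (any size; Gram statistics are size-agnostic).
#' @param cfg a [style_config()].
#' @param extractor optional extractor override (defaults to the frozen
#'   built-in one).
#' @return non-negative scalar loss.
#' @export
style_content_loss <- function(y, y_c, y_s, cfg = style_config(),
                               extractor = NULL) {
  if (length(cfg$feature_layers) == 0L) {
    stop("feature_layers must name at least one extractor layer", call. = FALSE)
  }
  stopifnot(identical(dim(y), dim(y_c)))
  ext <- extractor %||% build_feature_extractor(dim(y)[3])
  tc <- style_targets(y_c, cfg, ext, use_gram = cfg$content_gram)
  ts <- style_targets(y_s, cfg, ext, use_gram = TRUE)
  style_loss_grad(y, tc, ts, cfg, ext, want_grad = FALSE)$loss
}

# Gradient of the loss w.r.t. y (used by tests against finite differences).
style_content_loss_grad <- function(y, y_c, y_s, cfg = style_config(),
                                    extractor = NULL) {
  ext <- extractor %||% build_feature_extractor(dim(y)[3])
  tc <- style_targets(y_c, cfg, ext, use_gram = cfg$content_gram)
  ts <- style_targets(y_s, cfg, ext, use_gram = TRUE)
  style_loss_grad(y, tc, ts, cfg, ext, want_grad = TRUE)
}

#' Train a one-shot stylization generator
#'
#' Runs `cfg$iterations` SGD steps of the generator on one
#' (content, style) pair. With `init_weights` (warm start) the generator
#' resumes from a previous tile's weights, which typically starts at or
#' below the cold-start loss and converges faster.
#'
#' @param content_tile `H x W x 3` array in `[0, 1]`.
#' @param style_image `H x W x 3` array in `[0, 1]` (size may differ).
#' @param cfg a [style_config()].
#' @param init_weights optional `style_generator` to warm-start from.
#' @param seed weight-initialization seed (cold starts only).
#' @return list with `weights` (trained `style_generator`), `loss_trace`
#'   (loss before each step) and `y` (final stylized tile, clamped to
#'   `[0, 1]`).
#' @export
train_stylizer <- function(content_tile, style_image, cfg = style_config(),
                           init_weights = NULL, seed = 1L) {
  stopifnot(min(content_tile) >= 0, max(content_tile) <= 1)
  gen <- init_weights %||% build_generator(cfg$arch, size = dim(content_tile)[1:2],
                                           seed = seed)
  ext <- build_feature_extractor(dim(content_tile)[3])
  tc <- style_targets(content_tile, cfg, ext, use_gram = cfg$content_gram)
  ts <- style_targets(style_image, cfg, ext, use_gram = TRUE)
  trace <- numeric(0)
  lr <- cfg$learning_rate
  for (it in seq_len(cfg$iterations)) {
    fw <- generator_forward(gen, content_tile)
    lg <- style_loss_grad(fw$y, tc, ts, cfg, ext, want_grad = TRUE)
    if (!is.finite(lg$loss)) {
      stop(sprintf("non-finite loss at iteration %d (learning_rate = %g)",
                   it, lr), call. = FALSE)
    }
    trace <- c(trace, lg$loss)
    grads <- generator_backward(gen, fw$cache, lg$grad)
    for (nm in names(grads)) {
      gen$params[[nm]]$W <- gen$params[[nm]]$W - lr * grads[[nm]]$dW
      gen$params[[nm]]$b <- gen$params[[nm]]$b - lr * grads[[nm]]$db
    }
  }
  y <- clamp(generator_forward(gen, content_tile)$y, 0, 1)
  list(weights = gen, loss_trace = trace, y = y)
}

assemble_tile <- function(images) {
  k <- as.integer(sqrt(length(images)))
  S <- dim(images[[1]])[1]
  tile <- array(0, dim = c(k * S, k * S, 3L))
  for (i in seq_along(images)) {
    r <- (i - 1L) %/% k # row-major 2x2 layout
    c <- (i - 1L) %% k
    tile[r * S + seq_len(S), c * S + seq_len(S), ] <- images[[i]]
  }
  tile
}

split_tile <- function(tile, k, S) {
  lapply(seq_len(k * k), function(i) {
    r <- (i - 1L) %/% k
    c <- (i - 1L) %% k
    tile[r * S + seq_len(S), c * S + seq_len(S), , drop = FALSE]
  })
}

#' Stylize a batch of patches as one tile
#'
#' Assembles `patches_per_tile` equal-size patches into one square tile
#' (row-major), trains a one-shot stylizer on the tile against a single
#' style image, and splits the stylized tile back into patches.
#' Stylization is geometry-preserving: annotations and masks are copied
#' unchanged; only provenance (`style`) is updated.
#'
#' @param records list of exactly `cfg$patches_per_tile`
#'   `synth_patch_record`s with equal patch size.
#' @param style_image `H x W x 3` array, 0..255 scale.
#' @param cfg a [style_config()]; `cfg$tile_size` must equal
#'   `patch_size * sqrt(patches_per_tile)`.
#' @param init_weights optional warm-start generator.
#' @param seed cold-start initialization seed.
#' @param style_id provenance label for the style used.
#' @return list with `records` (stylized), `weights`, `loss_trace`.
#' @export
stylize_batch <- function(records, style_image, cfg = style_config(),
                          init_weights = NULL, seed = 1L,
                          style_id = "style") {
  if (length(records) != cfg$patches_per_tile) {
    stop(sprintf("expected %d patches per tile, got %d",
                 cfg$patches_per_tile, length(records)), call. = FALSE)
  }
  sizes <- vapply(records, function(r) dim(r$image)[1], numeric(1))
  widths <- vapply(records, function(r) dim(r$image)[2], numeric(1))
  if (length(unique(c(sizes, widths))) != 1L) {
    stop("all patches in a tile must be square and equal-sized", call. = FALSE)
  }
  S <- as.integer(sizes[1])
  k <- as.integer(sqrt(cfg$patches_per_tile))
  if (cfg$tile_size != k * S) {
    stop(sprintf("tile_size (%d) must equal patch_size * sqrt(patches_per_tile) = %d",
                 cfg$tile_size, k * S), call. = FALSE)
  }
  tile <- assemble_tile(lapply(records, function(r) r$image)) / 255
  fit <- train_stylizer(tile, clamp(style_image, 0, 255) / 255, cfg,
                        init_weights = init_weights, seed = seed)
  parts <- split_tile(fit$y * 255, k, S)
  out <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    rec$image <- round(parts[[i]])
    rec$provenance$style <- style_id
    rec
  })
  list(records = out, weights = fit$weights, loss_trace = fit$loss_trace)
}
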