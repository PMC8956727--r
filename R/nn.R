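# Minimal convolutional-network machinery used by the stylization stage:
# 3x3 same-padding convolutions, ReLU, 2x average pooling, nearest
# upsampling, all with hand-written backward passes. Tensors are numeric
# arrays H x W x C. This is deliberately small: the stylizer trains a tiny
# per-image generator, not a general deep-learning model.

as_mat <- function(x) {
  d <- dim(x)
  matrix(x, d[1] * d[2], d[3])
}

conv3_init <- function(cin, cout, seed = NULL, zero = FALSE) {
  w <- if (zero) {
    array(0, dim = c(3, 3, cin, cout))
  } else {
    array(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
          dim = c(3, 3, cin, cout))
  }
  list(W = w, b = rep(0, cout))
}

conv3_forward <- function(x, p) {
  d <- dim(x); H <- d[1]; W <- d[2]; cin <- d[3]
  cout <- dim(p$W)[4]
  xp <- array(0, dim = c(H + 2L, W + 2L, cin))
  xp[1L + seq_len(H), 1L + seq_len(W), ] <- x
  out <- matrix(rep(p$b, each = H * W), H * W, cout)
  for (dh in 0:2) {
    for (dw in 0:2) {
      xs <- xp[dh + seq_len(H), dw + seq_len(W), , drop = FALSE]
      wm <- matrix(p$W[dh + 1, dw + 1, , ], cin, cout)
      out <- out + as_mat(xs) %*% wm
    }
  }
  array(out, dim = c(H, W, cout))
}

conv3_backward <- function(dout, x, p) {
  d <- dim(x); H <- d[1]; W <- d[2]; cin <- d[3]
  cout <- dim(p$W)[4]
  xp <- array(0, dim = c(H + 2L, W + 2L, cin))
  xp[1L + seq_len(H), 1L + seq_len(W), ] <- x
  dm <- as_mat(dout)
  dW <- array(0, dim = dim(p$W))
  dxp <- array(0, dim = dim(xp))
  for (dh in 0:2) {
    for (dw in 0:2) {
      xs <- xp[dh + seq_len(H), dw + seq_len(W), , drop = FALSE]
      dW[dh + 1, dw + 1, , ] <- crossprod(as_mat(xs), dm)
      wm <- matrix(p$W[dh + 1, dw + 1, , ], cin, cout)
      dxs <- array(tcrossprod(dm, wm), dim = c(H, W, cin))
      dxp[dh + seq_len(H), dw + seq_len(W), ] <-
        dxp[dh + seq_len(H), dw + seq_len(W), , drop = FALSE] + dxs
    }
  }
  list(dx = dxp[1L + seq_len(H), 1L + seq_len(W), , drop = FALSE],
       dW = dW, db = colSums(dm))
}

relu_forward <- function(x) pmax(x, 0)
relu_backward <- function(dout, x) dout * (x > 0)

# 2x average pooling; odd trailing rows/cols are cropped.
pool2_forward <- function(x) {
  d <- dim(x)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  stopifnot(H2 >= 1L, W2 >= 1L)
  r1 <- seq.int(1L, by = 2L, length.out = H2)
  c1 <- seq.int(1L, by = 2L, length.out = W2)
  (x[r1, c1, , drop = FALSE] + x[r1 + 1L, c1, , drop = FALSE] +
     x[r1, c1 + 1L, , drop = FALSE] + x[r1 + 1L, c1 + 1L, , drop = FALSE]) / 4
}

pool2_backward <- function(dout, in_dim) {
  d <- dim(dout)
  dx <- array(0, dim = in_dim)
  r1 <- seq.int(1L, by = 2L, length.out = d[1])
  c1 <- seq.int(1L, by = 2L, length.out = d[2])
  g <- dout / 4
  dx[r1, c1, ] <- g
  dx[r1 + 1L, c1, ] <- g
  dx[r1, c1 + 1L, ] <- g
  dx[r1 + 1L, c1 + 1L, ] <- g
  dx
}

up2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

up2_backward <- function(dout) {
  d <- dim(dout)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  r1 <- seq.int(1L, by = 2L, length.out = H2)
  c1 <- seq.int(1L, by = 2L, length.out = W2)
  dout[r1, c1, , drop = FALSE] + dout[r1 + 1L, c1, , drop = FALSE] +
    dout[r1, c1 + 1L, , drop = FALSE] + dout[r1 + 1L, c1 + 1L, , drop = FALSE]
}

# ---- fixed feature extractor -----------------------------------------------
# A frozen, seeded random-weight convolutional pyramid: five 3x3 conv+ReLU
# blocks separated by 2x average pooling. Its Gram statistics play the role
# of a perceptual feature basis for the style/content losses; the weights
# are deterministic (fixed seed) and never trained.

.extractor_cache <- new.env(parent = emptyenv())

#' Build (or fetch) the frozen feature extractor
#'
#' @param in_channels number of input channels (3 for RGB; other values
#'   supported for low-dimensional gradient checks).
#' @return a `feature_extractor`: list of conv blocks named
#'   `block1`..`block5` with frozen weights.
#' @export
build_feature_extractor <- function(in_channels = 3L) {
  key <- as.character(in_channels)
  if (!is.null(.extractor_cache[[key]])) return(.extractor_cache[[key]])
  widths <- c(8L, 16L, 16L, 16L, 16L)
  ext <- with_seed(771177L + in_channels, {
    blocks <- list()
    cin <- in_channels
    for (i in seq_along(widths)) {
      blocks[[paste0("block", i)]] <- conv3_init(cin, widths[i])
      cin <- widths[i]
    }
    blocks
  })
  ext <- structure(ext, class = "feature_extractor")
  .extractor_cache[[key]] <- ext
  ext
}

# Forward pass up to the deepest requested block. Returns the tapped
# post-ReLU feature maps plus the caches needed for the backward pass.
extractor_forward <- function(ext, x, layers) {
  all_names <- names(ext)
  deepest <- max(match(layers, all_names))
  if (any(is.na(match(layers, all_names)))) {
    stop("unknown feature layers: ",
         paste(setdiff(layers, all_names), collapse = ", "), call. = FALSE)
  }
  feats <- list(); caches <- list()
  cur <- x
  for (i in seq_len(deepest)) {
    z <- conv3_forward(cur, ext[[i]])
    f <- relu_forward(z)
    caches[[i]] <- list(input = cur, pre = z, feat = f)
    feats[[all_names[i]]] <- f
    if (i < deepest) {
      if (dim(f)[1] < 2L || dim(f)[2] < 2L) {
        stop("input too small for feature layer ", all_names[i + 1], call. = FALSE)
      }
      cur <- pool2_forward(f)
    }
  }
  list(features = feats, caches = caches, deepest = deepest)
}

# Backward pass: dfeats is a named list of gradients w.r.t. the tapped
# feature maps (missing taps contribute zero). Returns d loss / d x.
extractor_backward <- function(ext, fw, dfeats) {
  all_names <- names(ext)
  grad <- NULL
  for (i in seq.int(fw$deepest, 1L)) {
    cache <- fw$caches[[i]]
    df <- dfeats[[all_names[i]]]
    dcur <- if (is.null(grad)) {
      array(0, dim = dim(cache$feat))
    } else {
      pool2_backward(grad, dim(cache$feat))
    }
    if (!is.null(df)) dcur <- dcur + df
    dz <- relu_backward(dcur, cache$pre)
    grad <- conv3_backward(dz, cache$input, ext[[i]])$dx
  }
  grad
}

# ---- generator networks ----------------------------------------------------

#' Build an image-generation network
#'
#' Both architectures map RGB to RGB at the input resolution and are
#' parameterized as `y = x + residual` with a zero-initialized output
#' convolution, so an untrained network is the identity (this stabilizes
#' warm starts). `highres` maintains a full-resolution branch alongside a
#' half-resolution one with cross-resolution fusion; `light` is a small
#' 3-level (full, 1/2, 1/4 scale) residual fully-convolutional net for
#' CPU-scale work.
#'
#' @param arch `"highres"` or `"light"`.
#' @param size input side in pixels; must be divisible by the
#'   architecture's stride (2 for `highres`, 4 for `light`).
#' @param seed weight-initialization seed.
#' @return a `style_generator` (list of conv parameter blocks).
#' @export
build_generator <- function(arch = c("highres", "light"), size,
                            seed = 1L) {
  arch <- match.arg(arch)
  stride <- if (arch == "light") 4L else 2L
  if (any(size %% stride != 0)) {
    stop(sprintf("size %s not divisible by the %s architecture's stride %d",
                 paste(size, collapse = "x"), arch, stride), call. = FALSE)
  }
  params <- with_seed(seed, {
    if (arch == "light") {
      C <- 8L
      list(enc0 = conv3_init(3L, C), enc1 = conv3_init(C, C),
           enc2 = conv3_init(C, C), dec1 = conv3_init(C, C),
           dec0 = conv3_init(C, C), out = conv3_init(C, 3L, zero = TRUE))
    } else {
      C <- 12L
      list(full1 = conv3_init(3L, C), half1 = conv3_init(3L, C),
           full2 = conv3_init(C, C), half2 = conv3_init(C, C),
           full3 = conv3_init(C, C), out = conv3_init(C, 3L, zero = TRUE))
    }
  })
  structure(list(arch = arch, stride = stride, params = params),
            class = "style_generator")
}

#' Number of trainable parameters of a generator
#' @param gen a `style_generator`.
#' @return integer count.
#' @export
generator_n_params <- function(gen) {
  sum(vapply(gen$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

generator_forward <- function(gen, x) {
  p <- gen$params
  if (gen$arch == "light") {
    z0 <- conv3_forward(x, p$enc0); c0 <- relu_forward(z0)
    d0 <- pool2_forward(c0)
    z1 <- conv3_forward(d0, p$enc1); c1 <- relu_forward(z1)
    d1 <- pool2_forward(c1)
    z2 <- conv3_forward(d1, p$enc2); c2 <- relu_forward(z2)
    u1 <- up2_forward(c2)
    m1 <- c1 + u1
    z3 <- conv3_forward(m1, p$dec1); c3 <- relu_forward(z3)
    u0 <- up2_forward(c3)
    m0 <- c0 + u0
    z4 <- conv3_forward(m0, p$dec0); c4 <- relu_forward(z4)
    r <- conv3_forward(c4, p$out)
    y <- x + r
    list(y = y, cache = list(x = x, z0 = z0, c0 = c0, d0 = d0, z1 = z1,
                             c1 = c1, d1 = d1, z2 = z2, c2 = c2, m1 = m1,
                             z3 = z3, c3 = c3, m0 = m0, z4 = z4, c4 = c4))
  } else {
    xp <- pool2_forward(x)
    zf1 <- conv3_forward(x, p$full1); f1 <- relu_forward(zf1)
    zh1 <- conv3_forward(xp, p$half1); h1 <- relu_forward(zh1)
    mf2 <- f1 + up2_forward(h1)
    mh2 <- pool2_forward(f1) + h1
    zf2 <- conv3_forward(mf2, p$full2); f2 <- relu_forward(zf2)
    zh2 <- conv3_forward(mh2, p$half2); h2 <- relu_forward(zh2)
    mf3 <- f2 + up2_forward(h2)
    zf3 <- conv3_forward(mf3, p$full3); f3 <- relu_forward(zf3)
    r <- conv3_forward(f3, p$out)
    y <- x + r
    list(y = y, cache = list(x = x, xp = xp, zf1 = zf1, f1 = f1, zh1 = zh1,
                             h1 = h1, mf2 = mf2, mh2 = mh2, zf2 = zf2,
                             f2 = f2, zh2 = zh2, h2 = h2, mf3 = mf3,
                             zf3 = zf3, f3 = f3))
  }
}

generator_backward <- function(gen, cache, dy) {
  p <- gen$params
  g <- list()
  if (gen$arch == "light") {
    bo <- conv3_backward(dy, cache$c4, p$out)
    g$out <- bo[c("dW", "db")]
    dz4 <- relu_backward(bo$dx, cache$z4)
    b4 <- conv3_backward(dz4, cache$m0, p$dec0)
    g$dec0 <- b4[c("dW", "db")]
    dm0 <- b4$dx
    dc0 <- dm0
    dc3 <- up2_backward(dm0)
    dz3 <- relu_backward(dc3, cache$z3)
    b3 <- conv3_backward(dz3, cache$m1, p$dec1)
    g$dec1 <- b3[c("dW", "db")]
    dm1 <- b3$dx
    dc1 <- dm1
    dc2 <- up2_backward(dm1)
    dz2 <- relu_backward(dc2, cache$z2)
    b2 <- conv3_backward(dz2, cache$d1, p$enc2)
    g$enc2 <- b2[c("dW", "db")]
    dc1 <- dc1 + pool2_backward(b2$dx, dim(cache$c1))
    dz1 <- relu_backward(dc1, cache$z1)
    b1 <- conv3_backward(dz1, cache$d0, p$enc1)
    g$enc1 <- b1[c("dW", "db")]
    dc0 <- dc0 + pool2_backward(b1$dx, dim(cache$c0))
    dz0 <- relu_backward(dc0, cache$z0)
    b0 <- conv3_backward(dz0, cache$x, p$enc0)
    g$enc0 <- b0[c("dW", "db")]
  } else {
    bo <- conv3_backward(dy, cache$f3, p$out)
    g$out <- bo[c("dW", "db")]
    dzf3 <- relu_backward(bo$dx, cache$zf3)
    b3 <- conv3_backward(dzf3, cache$mf3, p$full3)
    g$full3 <- b3[c("dW", "db")]
    df2 <- b3$dx
    dh2 <- up2_backward(b3$dx)
    dzf2 <- relu_backward(df2, cache$zf2)
    b2f <- conv3_backward(dzf2, cache$mf2, p$full2)
    g$full2 <- b2f[c("dW", "db")]
    dzh2 <- relu_backward(dh2, cache$zh2)
    b2h <- conv3_backward(dzh2, cache$mh2, p$half2)
    g$half2 <- b2h[c("dW", "db")]
    df1 <- b2f$dx + pool2_backward(b2h$dx, dim(cache$f1))
    dh1 <- up2_backward(b2f$dx) + b2h$dx
    dzf1 <- relu_backward(df1, cache$zf1)
    b1f <- conv3_backward(dzf1, cache$x, p$full1)
    g$full1 <- b1f[c("dW", "db")]
    dzh1 <- relu_backward(dh1, cache$zh1)
    b1h <- conv3_backward(dzh1, cache$xp, p$half1)
    g$half1 <- b1h[c("dW", "db")]
  }
  g
}
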