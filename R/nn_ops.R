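# Differentiable primitives for the segmentation network.
#
# Feature maps are dense arrays with dim = c(H, W, C, N).  Each primitive has
# a forward function returning list(y, cache) and a backward function taking
# the cache and the upstream gradient.  Parameters live in a flat named list
# on the model; gradients are accumulated into an environment keyed by the
# same names.

as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

# He-initialized convolution parameters: w ~ N(0, sqrt(2 / fan_in)), b = 0.
# fan_in = kh * kw * cin, the defining scale for rectifier networks.
conv_params <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  w <- array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
             dim = c(kh, kw, cin, cout))
  list(w = w, b = numeric(cout))
}

conv_fw <- function(params, name, x, stride = 1L, dilation = 1L, pad = NULL) {
  w <- params[[paste0(name, ".w")]]
  b <- params[[paste0(name, ".b")]]
  wd <- dim(w)
  if (is.null(pad)) pad <- (dilation * (wd[1] - 1L)) %/% 2L  # "same" for stride 1
  y <- cpp_conv2d_forward(x, dim(x), w, wd, b,
                          as.integer(stride), as.integer(dilation), as.integer(pad))
  list(y = y, cache = list(x = x, name = name, stride = stride,
                           dilation = dilation, pad = pad))
}

conv_bw <- function(grads, params, cache, gy) {
  w <- params[[paste0(cache$name, ".w")]]
  res <- cpp_conv2d_backward(cache$x, dim(cache$x), w, dim(w), gy,
                             as.integer(cache$stride), as.integer(cache$dilation),
                             as.integer(cache$pad))
  nw <- paste0(cache$name, ".w"); nb <- paste0(cache$name, ".b")
  grads[[nw]] <- if (is.null(grads[[nw]])) res$gw else grads[[nw]] + res$gw
  grads[[nb]] <- if (is.null(grads[[nb]])) res$gb else grads[[nb]] + res$gb
  res$gx
}

# Randomized leaky ReLU.  Training draws the negative slope elementwise from
# U(lower, upper); evaluation uses the deterministic midpoint slope.
rrelu_fw <- function(x, lower, upper, training) {
  neg <- which(x < 0)
  slope <- if (training && length(neg) > 0)
    stats::runif(length(neg), lower, upper)
  else (lower + upper) / 2
  y <- x
  if (length(neg) > 0)
    y[neg] <- x[neg] * if (training) slope else slope[1]
  list(y = y, cache = list(neg = neg, slope = slope))
}

rrelu_bw <- function(cache, gy) {
  gx <- gy
  if (length(cache$neg) > 0)
    gx[cache$neg] <- gy[cache$neg] * cache$slope
  gx
}

sigmoid_fw <- function(x) {
  # clamp away from {0, 1} so downstream logarithms and the open-interval
  # output contract survive float saturation of extreme logits
  y <- pmin(pmax(1 / (1 + exp(-x)), 1e-7), 1 - 1e-7)
  list(y = y, cache = y)
}

sigmoid_bw <- function(cache, gy) gy * cache * (1 - cache)

# Global average pooling [H,W,C,N] -> [C,N]
gap_fw <- function(x) {
  d <- dim(x)
  v <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  list(y = matrix(v, d[3], d[4]), cache = d)
}

gap_bw <- function(cache, gy) {
  d <- cache
  array(rep(gy, each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
}

# 1x1 "convolution" on channel vectors: params w [Cout, Cin], b [Cout];
# input X is [Cin, N].
vconv_params <- function(cin, cout) {
  list(w = matrix(stats::rnorm(cout * cin, sd = sqrt(2 / cin)), cout, cin),
       b = numeric(cout))
}

vconv_fw <- function(params, name, X) {
  w <- params[[paste0(name, ".w")]]
  b <- params[[paste0(name, ".b")]]
  list(y = w %*% X + b, cache = list(X = X, name = name))
}

vconv_bw <- function(grads, params, cache, gy) {
  w <- params[[paste0(cache$name, ".w")]]
  nw <- paste0(cache$name, ".w"); nb <- paste0(cache$name, ".b")
  gw <- gy %*% t(cache$X)
  gb <- rowSums(gy)
  grads[[nw]] <- if (is.null(grads[[nw]])) gw else grads[[nw]] + gw
  grads[[nb]] <- if (is.null(grads[[nb]])) gb else grads[[nb]] + gb
  t(w) %*% gy
}

# Batch normalization over the batch dimension of a [C, N] matrix.
# Running statistics live in the model's buffer environment, not in the
# trainable parameter list.
bn_params <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

bn_fw <- function(params, buffers, name, X, training, momentum = 0.1, eps = 1e-5) {
  gamma <- params[[paste0(name, ".gamma")]]
  beta <- params[[paste0(name, ".beta")]]
  key_m <- paste0(name, ".running_mean"); key_v <- paste0(name, ".running_var")
  if (is.null(buffers[[key_m]])) {
    buffers[[key_m]] <- numeric(length(gamma))
    buffers[[key_v]] <- rep(1, length(gamma))
  }
  if (training) {
    mu <- rowMeans(X)
    va <- rowMeans((X - mu)^2)
    buffers[[key_m]] <- (1 - momentum) * buffers[[key_m]] + momentum * mu
    buffers[[key_v]] <- (1 - momentum) * buffers[[key_v]] + momentum * va
  } else {
    mu <- buffers[[key_m]]
    va <- buffers[[key_v]]
  }
  inv_std <- 1 / sqrt(va + eps)
  xhat <- (X - mu) * inv_std
  list(y = gamma * xhat + beta,
       cache = list(xhat = xhat, inv_std = inv_std, gamma = gamma,
                    name = name, training = training, n = ncol(X)))
}

bn_bw <- function(grads, params, cache, gy) {
  ng <- paste0(cache$name, ".gamma"); nb <- paste0(cache$name, ".beta")
  ggamma <- rowSums(gy * cache$xhat)
  gbeta <- rowSums(gy)
  grads[[ng]] <- if (is.null(grads[[ng]])) ggamma else grads[[ng]] + ggamma
  grads[[nb]] <- if (is.null(grads[[nb]])) gbeta else grads[[nb]] + gbeta
  gxhat <- gy * cache$gamma
  if (cache$training) {
    n <- cache$n
    gx <- cache$inv_std / n *
      (n * gxhat - rowSums(gxhat) - cache$xhat * rowSums(gxhat * cache$xhat))
  } else {
    gx <- gxhat * cache$inv_std
  }
  gx
}

upsample2_fw <- function(x) {
  list(y = cpp_upsample2_forward(x, dim(x)), cache = dim(x))
}

upsample2_bw <- function(cache, gy) cpp_upsample2_backward(gy, cache)

# Per-channel gating: y[h,w,c,n] = x[h,w,c,n] * g[c,n]
scale_fw <- function(x, g) {
  d <- dim(x)
  g4 <- array(rep(g, each = d[1] * d[2]), dim = d)
  list(y = x * g4, cache = list(x = x, g4 = g4, d = d))
}

scale_bw <- function(cache, gy) {
  d <- cache$d
  gg <- colSums(matrix(gy * cache$x, d[1] * d[2], d[3] * d[4]))
  list(gx = gy * cache$g4, gg = matrix(gg, d[3], d[4]))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

split_channels <- function(gy, c1) {
  d <- dim(gy)
  list(a = array(gy[, , seq_len(c1), , drop = FALSE], c(d[1], d[2], c1, d[4])),
       b = array(gy[, , (c1 + 1):d[3], , drop = FALSE], c(d[1], d[2], d[3] - c1, d[4])))
}

# ---- Adam optimizer over a flat named parameter list -----------------------

adam_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}

new_grads <- function() new.env(parent = emptyenv())
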