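# The feature-fusion U-Net: encoder stages of MSFF blocks with stride-2
# convolutional downsampling (no pooling anywhere), a bottleneck MSFF block,
# and decoder stages that fuse each skip connection with the upsampled
# lower-resolution decoder through contextual channel attention (CCA).
# All activations are randomized leaky ReLUs; weights are He-initialized.

#' Architecture configuration
#'
#' All hyperparameters the architecture leaves open. The network downsamples
#' `depth` times by stride-2 convolution, doubling the channel width each
#' stage starting from `base_channels`.
#'
#' @param depth Number of downsampling stages (encoder depth).
#' @param base_channels Channel width at full resolution. Must be at least 9
#'   so that every MSFF splitting step retains a nonzero channel group.
#' @param reduction_r Squeeze ratio of the CCA attention bottleneck.
#' @param dilation_rate Dilation of the MSFF entry convolution.
#' @param rrelu_lower,rrelu_upper Bounds of the uniform distribution the
#'   randomized leaky ReLU draws its negative slope from during training; at
#'   evaluation the deterministic midpoint slope is used.
#' @param out_classes Number of sigmoid output maps (1 for per-lesion binary
#'   training, 4 for a multi-label head).
#' @param in_channels Number of input image channels.
#' @param gate Activation applied to the summed channel-attention vectors:
#'   `"rrelu"` (the published form) or `"sigmoid"` (bounded-gate ablation).
#' @return A `ffunet_config` list.
#' @export
ffunet_config <- function(depth = 4L, base_channels = 16L, reduction_r = 2L,
                          dilation_rate = 2L, rrelu_lower = 1 / 8,
                          rrelu_upper = 1 / 3, out_classes = 1L,
                          in_channels = 3L, gate = c("rrelu", "sigmoid")) {
  gate <- match.arg(gate)
  stopifnot(depth >= 1L, base_channels >= 9L, reduction_r >= 1L,
            dilation_rate >= 1L, out_classes >= 1L, in_channels >= 1L)
  if (!(rrelu_lower >= 0 && rrelu_lower < rrelu_upper && rrelu_upper <= 1))
    stop("require 0 <= rrelu_lower < rrelu_upper <= 1")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 reduction_r = as.integer(reduction_r),
                 dilation_rate = as.integer(dilation_rate),
                 rrelu_lower = rrelu_lower, rrelu_upper = rrelu_upper,
                 out_classes = as.integer(out_classes),
                 in_channels = as.integer(in_channels), gate = gate),
            class = "ffunet_config")
}

#' MSFF channel bookkeeping
#'
#' The splitting schedule of an MSFF block: step k takes its C_k input
#' channels, retains floor(C_k / 3) of them through a 3x3 convolution and
#' passes the remaining C_k - floor(C_k / 3) on through a 5x5 convolution.
#' After three steps the three retained groups plus the final pass-on group
#' are concatenated; by construction their widths always sum back to C.
#'
#' @param channels Channel count entering the splitting cascade.
#' @return List with `retained` (length 3), `passed` (length 3) and `concat`
#'   (the reassembled width, always equal to `channels`).
#' @export
msff_split_widths <- function(channels) {
  stopifnot(channels >= 9L)
  c1 <- as.integer(channels)
  r1 <- c1 %/% 3L; c2 <- c1 - r1
  r2 <- c2 %/% 3L; c3 <- c2 - r2
  r3 <- c3 %/% 3L; p3 <- c3 - r3
  list(retained = c(r1, r2, r3), passed = c(c2, c3, p3),
       concat = r1 + r2 + r3 + p3)
}

# ---- parameter construction ------------------------------------------------

msff_add_params <- function(P, prefix, cin, cout, dilation) {
  wd <- msff_split_widths(cin)
  P[paste0(prefix, ".entry.", c("w", "b"))] <- conv_params(3, 3, cin, cin)
  ck <- cin
  for (k in 1:3) {
    P[paste0(prefix, ".split", k, ".ret.", c("w", "b"))] <-
      conv_params(3, 3, ck, wd$retained[k])
    P[paste0(prefix, ".split", k, ".pass.", c("w", "b"))] <-
      conv_params(5, 5, ck, wd$passed[k])
    ck <- wd$passed[k]
  }
  P[paste0(prefix, ".reduce.", c("w", "b"))] <- conv_params(1, 1, cin, cout)
  if (cin != cout)
    P[paste0(prefix, ".proj.", c("w", "b"))] <- conv_params(1, 1, cin, cout)
  P
}

cca_add_params <- function(P, prefix, c_low, c, r) {
  cr <- max(1L, c %/% r)
  P[paste0(prefix, ".proj.", c("w", "b"))] <- conv_params(1, 1, c_low, c)
  for (path in c("ld", "sk")) {
    P[paste0(prefix, ".", path, ".conv1.", c("w", "b"))] <- vconv_params(c, cr)
    P[paste0(prefix, ".", path, ".bn.", c("gamma", "beta"))] <- bn_params(cr)
    P[paste0(prefix, ".", path, ".conv2.", c("w", "b"))] <- vconv_params(cr, c)
  }
  P
}

#' Build the segmentation network
#'
#' Allocates and He-initializes all parameters of the encoder-decoder
#' described by `config`. The returned model is a plain list holding the
#' configuration, a flat named list of parameter arrays, and an environment
#' of batch-normalization running statistics.
#'
#' @param config A [ffunet_config()].
#' @param seed Integer seed fixing the weight initialization.
#' @return A `ffunet_model` object.
#' @export
build_ffunet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ffunet_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  d <- config$depth
  ch <- config$base_channels * 2L^(0:d)  # ch[i] = width at encoder stage i
  P <- list()
  P[c("stem.w", "stem.b")] <- conv_params(3, 3, config$in_channels, ch[1])
  for (i in seq_len(d)) {
    P <- msff_add_params(P, paste0("enc", i, ".msff"), ch[i], ch[i],
                         config$dilation_rate)
    P[paste0("enc", i, ".down.", c("w", "b"))] <- conv_params(3, 3, ch[i], ch[i + 1])
  }
  P <- msff_add_params(P, "bottleneck.msff", ch[d + 1], ch[d + 1],
                       config$dilation_rate)
  for (j in seq_len(d)) {
    c_low <- ch[d + 2L - j]
    c_skip <- ch[d + 1L - j]
    P <- cca_add_params(P, paste0("dec", j, ".cca"), c_low, c_skip,
                        config$reduction_r)
    P[paste0("dec", j, ".fuse.", c("w", "b"))] <- conv_params(3, 3, 2L * c_skip, c_skip)
  }
  P[c("head.w", "head.b")] <- conv_params(1, 1, ch[1], config$out_classes)
  structure(list(config = config, params = P,
                 buffers = new.env(parent = emptyenv())),
            class = "ffunet_model")
}

#' Count learnable parameters
#'
#' @param model A `ffunet_model`.
#' @return Total number of learnable scalars (running statistics excluded).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ffunet_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.ffunet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Feature-fusion U-Net: depth %d, base width %d, ",
                     "%d output map(s), %s gate\n  %s parameters\n"),
              cfg$depth, cfg$base_channels, cfg$out_classes, cfg$gate,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- MSFF block forward/backward -------------------------------------------

msff_fw <- function(params, prefix, x, config, training) {
  cin <- dim(x)[3]
  wd <- msff_split_widths(cin)
  lo <- config$rrelu_lower; up <- config$rrelu_upper
  cv <- conv_fw(params, paste0(prefix, ".entry"), x, dilation = config$dilation_rate)
  ac <- rrelu_fw(cv$y, lo, up, training)
  caches <- list(entry = cv$cache, entry_act = ac$cache)
  h <- ac$y
  retained <- vector("list", 3)
  for (k in 1:3) {
    rc <- conv_fw(params, paste0(prefix, ".split", k, ".ret"), h)
    ra <- rrelu_fw(rc$y, lo, up, training)
    pc <- conv_fw(params, paste0(prefix, ".split", k, ".pass"), h)
    pa <- rrelu_fw(pc$y, lo, up, training)
    caches[[paste0("ret", k)]] <- rc$cache
    caches[[paste0("ret", k, "_act")]] <- ra$cache
    caches[[paste0("pass", k)]] <- pc$cache
    caches[[paste0("pass", k, "_act")]] <- pa$cache
    retained[[k]] <- ra$y
    h <- pa$y
  }
  cat1 <- concat_channels(retained[[1]], retained[[2]])
  cat2 <- concat_channels(cat1, retained[[3]])
  cat3 <- concat_channels(cat2, h)
  rd <- conv_fw(params, paste0(prefix, ".reduce"), cat3)
  has_proj <- !is.null(params[[paste0(prefix, ".proj.w")]])
  if (has_proj) {
    pj <- conv_fw(params, paste0(prefix, ".proj"), x)
    resid <- pj$y
    caches$proj <- pj$cache
  } else {
    resid <- x
  }
  out_act <- rrelu_fw(rd$y + resid, lo, up, training)
  caches$reduce <- rd$cache
  caches$out_act <- out_act$cache
  caches$widths <- wd
  caches$has_proj <- has_proj
  list(y = out_act$y, cache = caches)
}

msff_bw <- function(grads, params, prefix, cache, gy) {
  wd <- cache$widths
  g <- rrelu_bw(cache$out_act, gy)
  # residual branch
  if (cache$has_proj) {
    gx_res <- conv_bw(grads, params, cache$proj, g)
  } else {
    gx_res <- g
  }
  gcat <- conv_bw(grads, params, cache$reduce, g)
  # un-concatenate: retained1, retained2, retained3, final pass-on
  r <- wd$retained
  sp3 <- split_channels(gcat, r[1] + r[2] + r[3])
  g_pass_final <- sp3$b
  sp2 <- split_channels(sp3$a, r[1] + r[2])
  g_ret3 <- sp2$b
  sp1 <- split_channels(sp2$a, r[1])
  g_ret1 <- sp1$a
  g_ret2 <- sp1$b
  g_ret <- list(g_ret1, g_ret2, g_ret3)
  # walk the splitting cascade backwards
  g_h <- g_pass_final
  for (k in 3:1) {
    g_pc <- rrelu_bw(cache[[paste0("pass", k, "_act")]], g_h)
    g_in_pass <- conv_bw(grads, params, cache[[paste0("pass", k)]], g_pc)
    g_rc <- rrelu_bw(cache[[paste0("ret", k, "_act")]], g_ret[[k]])
    g_in_ret <- conv_bw(grads, params, cache[[paste0("ret", k)]], g_rc)
    g_h <- g_in_pass + g_in_ret
  }
  g_entry <- rrelu_bw(cache$entry_act, g_h)
  gx <- conv_bw(grads, params, cache$entry, g_entry)
  gx + gx_res
}

# ---- CCA fusion forward/backward -------------------------------------------

# LD: lower-resolution decoder features [h/2, w/2, c_low, n]
# SK: skip connection [h, w, c, n]
# Returns the 2c-channel fused map F = concat(gate * LD', gate * SK).
cca_fw <- function(params, buffers, prefix, LD, SK, config, training) {
  lo <- config$rrelu_lower; up <- config$rrelu_upper
  upc <- upsample2_fw(LD)
  pj <- conv_fw(params, paste0(prefix, ".proj"), upc$y)
  ldp <- pj$y
  att <- function(path, x4) {
    gp <- gap_fw(x4)
    c1 <- vconv_fw(params, paste0(prefix, ".", path, ".conv1"), gp$y)
    bn <- bn_fw(params, buffers, paste0(prefix, ".", path, ".bn"), c1$y, training)
    ac <- rrelu_fw(bn$y, lo, up, training)
    c2 <- vconv_fw(params, paste0(prefix, ".", path, ".conv2"), ac$y)
    list(y = c2$y, cache = list(gap = gp$cache, c1 = c1$cache, bn = bn$cache,
                                act = ac$cache, c2 = c2$cache))
  }
  a_ld <- att("ld", ldp)
  a_sk <- att("sk", SK)
  s <- a_ld$y + a_sk$y
  if (config$gate == "sigmoid") {
    gt <- sigmoid_fw(s)
  } else {
    gt <- rrelu_fw(s, lo, up, training)
  }
  s_ld <- scale_fw(ldp, gt$y)
  s_sk <- scale_fw(SK, gt$y)
  f <- concat_channels(s_ld$y, s_sk$y)
  list(y = f,
       cache = list(up = upc$cache, proj = pj$cache, a_ld = a_ld$cache,
                    a_sk = a_sk$cache, gate = gt$cache,
                    s_ld = s_ld$cache, s_sk = s_sk$cache,
                    c = dim(SK)[3], gate_kind = config$gate))
}

cca_bw <- function(grads, params, prefix, cache, gy) {
  sp <- split_channels(gy, cache$c)
  b_ld <- scale_bw(cache$s_ld, sp$a)
  b_sk <- scale_bw(cache$s_sk, sp$b)
  g_gate <- b_ld$gg + b_sk$gg
  if (cache$gate_kind == "sigmoid") {
    g_s <- sigmoid_bw(cache$gate, g_gate)
  } else {
    g_s <- rrelu_bw(cache$gate, g_gate)
  }
  att_bw <- function(path, acache, g_vec) {
    g2 <- vconv_bw(grads, params, acache$c2, g_vec)
    ga <- rrelu_bw(acache$act, g2)
    gb <- bn_bw(grads, params, acache$bn, ga)
    g1 <- vconv_bw(grads, params, acache$c1, gb)
    gap_bw(acache$gap, g1)
  }
  g_ldp <- b_ld$gx + att_bw("ld", cache$a_ld, g_s)
  g_sk <- b_sk$gx + att_bw("sk", cache$a_sk, g_s)
  g_up <- conv_bw(grads, params, cache$proj, g_ldp)
  g_LD <- upsample2_bw(cache$up, g_up)
  list(g_LD = g_LD, g_SK = g_sk)
}

# ---- full network ----------------------------------------------------------

#' Forward pass of the segmentation network
#'
#' @param model A built `ffunet_model`.
#' @param x Input batch: array `[H, W, in_channels, N]` (or `[H, W, C]` for a
#'   single image). Spatial dimensions must be divisible by `2^depth`.
#' @param training If `TRUE` the randomized activations draw stochastic
#'   slopes and batch normalization uses batch statistics; if `FALSE` the
#'   pass is fully deterministic.
#' @param with_cache Keep intermediate activations for a backward pass.
#' @return Sigmoid probability maps `[H, W, out_classes, N]`; with
#'   `with_cache = TRUE`, a list `(y, cache)`.
#' @export
ffunet_forward <- function(model, x, training = FALSE, with_cache = FALSE) {
  stopifnot(inherits(model, "ffunet_model"))
  x <- as_feature_map(x)
  cfg <- model$config
  d <- dim(x)
  div <- 2L^cfg$depth
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf("input %dx%d not divisible by %d (= 2^depth)", d[1], d[2], div))
  if (d[3] != cfg$in_channels)
    stop(sprintf("expected %d input channels, got %d", cfg$in_channels, d[3]))
  P <- model$params; B <- model$buffers
  lo <- cfg$rrelu_lower; up <- cfg$rrelu_upper
  caches <- list()

  st <- conv_fw(P, "stem", x)
  sa <- rrelu_fw(st$y, lo, up, training)
  caches$stem <- st$cache; caches$stem_act <- sa$cache
  h <- sa$y
  skips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    m <- msff_fw(P, paste0("enc", i, ".msff"), h, cfg, training)
    caches[[paste0("enc", i, ".msff")]] <- m$cache
    skips[[i]] <- m$y
    dn <- conv_fw(P, paste0("enc", i, ".down"), m$y, stride = 2L)
    da <- rrelu_fw(dn$y, lo, up, training)
    caches[[paste0("enc", i, ".down")]] <- dn$cache
    caches[[paste0("enc", i, ".down_act")]] <- da$cache
    h <- da$y
  }
  bt <- msff_fw(P, "bottleneck.msff", h, cfg, training)
  caches$bottleneck <- bt$cache
  h <- bt$y
  for (j in seq_len(cfg$depth)) {
    sk <- skips[[cfg$depth + 1L - j]]
    cc <- cca_fw(P, B, paste0("dec", j, ".cca"), h, sk, cfg, training)
    fu <- conv_fw(P, paste0("dec", j, ".fuse"), cc$y)
    fa <- rrelu_fw(fu$y, lo, up, training)
    caches[[paste0("dec", j, ".cca")]] <- cc$cache
    caches[[paste0("dec", j, ".fuse")]] <- fu$cache
    caches[[paste0("dec", j, ".fuse_act")]] <- fa$cache
    h <- fa$y
  }
  hd <- conv_fw(P, "head", h)
  sg <- sigmoid_fw(hd$y)
  caches$head <- hd$cache; caches$head_act <- sg$cache
  if (with_cache) list(y = sg$y, cache = caches) else sg$y
}

# Backpropagate dL/dQ through the cached forward pass; returns an
# environment of parameter gradients keyed like model$params.
ffunet_backward <- function(model, cache, gq) {
  cfg <- model$config
  P <- model$params
  grads <- new_grads()
  g <- sigmoid_bw(cache$head_act, gq)
  g <- conv_bw(grads, P, cache$head, g)
  g_skips <- vector("list", cfg$depth)
  for (j in rev(seq_len(cfg$depth))) {
    g <- rrelu_bw(cache[[paste0("dec", j, ".fuse_act")]], g)
    g <- conv_bw(grads, P, cache[[paste0("dec", j, ".fuse")]], g)
    cc <- cca_bw(grads, P, paste0("dec", j, ".cca"),
                 cache[[paste0("dec", j, ".cca")]], g)
    g_skips[[cfg$depth + 1L - j]] <- cc$g_SK
    g <- cc$g_LD
  }
  g <- msff_bw(grads, P, "bottleneck.msff", cache$bottleneck, g)
  for (i in rev(seq_len(cfg$depth))) {
    g <- rrelu_bw(cache[[paste0("enc", i, ".down_act")]], g)
    g <- conv_bw(grads, P, cache[[paste0("enc", i, ".down")]], g)
    g <- g + g_skips[[i]]
    g <- msff_bw(grads, P, paste0("enc", i, ".msff"),
                 cache[[paste0("enc", i, ".msff")]], g)
  }
  g <- rrelu_bw(cache$stem_act, g)
  conv_bw(grads, P, cache$stem, g)
  grads
}

# ---- standalone building blocks (usable outside the full network) ----------

#' Stride-2 convolutional downsampling
#'
#' A learned 3x3 stride-2 convolution halving the spatial dimensions; the
#' network uses this everywhere a classical U-Net would max-pool.
#'
#' @param x Feature map `[H, W, C, N]` with even `H`, `W`.
#' @param out_channels Output channel count.
#' @param seed Seed for the He initialization.
#' @param bias Include a bias term.
#' @return Feature map `[H/2, W/2, out_channels, N]`.
#' @export
downsample <- function(x, out_channels, seed = 1L, bias = TRUE) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("downsample requires even spatial dimensions")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  P <- list()
  P[c("down.w", "down.b")] <- conv_params(3, 3, d[3], out_channels)
  if (!bias) P[["down.b"]] <- numeric(out_channels)
  conv_fw(P, "down", x, stride = 2L, pad = 1L)$y
}

#' Standalone MSFF block
#'
#' Builds one multiscale feature-fusion block (dilated entry convolution,
#' three channel-splitting steps, 1x1 reduction, residual skip) with its own
#' He-initialized parameters, for inspection and testing outside the full
#' network.
#'
#' @param channels_in Input channel count (>= 9).
#' @param out_channels Output channel count.
#' @param dilation_rate Dilation of the entry convolution.
#' @param seed Initialization seed.
#' @return An object usable with [msff_forward()]; its `$params` may be
#'   modified in place.
#' @export
msff_block <- function(channels_in, out_channels, dilation_rate = 2L, seed = 1L) {
  if (channels_in < 9L)
    stop("MSFF requires at least 9 input channels so each splitting step retains >= 1")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  cfg <- ffunet_config(depth = 1L, base_channels = max(9L, channels_in),
                       dilation_rate = dilation_rate)
  P <- msff_add_params(list(), "msff", channels_in, out_channels, dilation_rate)
  structure(list(params = P, config = cfg, channels_in = channels_in,
                 out_channels = out_channels), class = "msff_block")
}

#' Apply a standalone MSFF block
#'
#' @param block A [msff_block()].
#' @param x Feature map `[H, W, channels_in, N]`.
#' @param training Use stochastic activation slopes.
#' @return Feature map `[H, W, out_channels, N]` of unchanged spatial size.
#' @export
msff_forward <- function(block, x, training = FALSE) {
  stopifnot(inherits(block, "msff_block"))
  x <- as_feature_map(x)
  if (dim(x)[3] != block$channels_in) stop("channel mismatch")
  msff_fw(block$params, "msff", x, block$config, training)$y
}

#' Standalone CCA fusion module
#'
#' Contextual channel attention over a lower-resolution decoder map `LD` and
#' a skip connection `SK`: LD is bilinearly upsampled and 1x1-projected to
#' SK's channel count; both maps are globally average-pooled and passed
#' through a squeeze (1x1 conv + batch norm to c/r channels), an RReLU and an
#' expand (1x1 conv back to c); the two attention vectors are summed, gated,
#' and the gate rescales both full-resolution maps channel-wise before
#' concatenation.
#'
#' @param channels Channel count `c` of the skip connection.
#' @param channels_ld Channel count of the lower-resolution decoder input
#'   (before projection); defaults to `2 * channels`.
#' @param reduction_r Squeeze ratio.
#' @param gate `"rrelu"` (default) or `"sigmoid"`.
#' @param seed Initialization seed.
#' @return An object usable with [cca_fuse()].
#' @export
cca_module <- function(channels, channels_ld = 2L * channels, reduction_r = 2L,
                       gate = c("rrelu", "sigmoid"), seed = 1L) {
  gate <- match.arg(gate)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  cfg <- ffunet_config(depth = 1L, reduction_r = reduction_r, gate = gate)
  P <- cca_add_params(list(), "cca", channels_ld, channels, reduction_r)
  structure(list(params = P, config = cfg, channels = channels,
                 buffers = new.env(parent = emptyenv())), class = "cca_module")
}

#' Fuse decoder and skip features with contextual channel attention
#'
#' @param module A [cca_module()].
#' @param LD Lower-resolution decoder map `[h/2, w/2, channels_ld, N]`.
#' @param SK Skip connection `[h, w, channels, N]`.
#' @param training Use batch statistics and stochastic activation slopes.
#' @return Fused map `[h, w, 2 * channels, N]`.
#' @export
cca_fuse <- function(module, LD, SK, training = FALSE) {
  stopifnot(inherits(module, "cca_module"))
  LD <- as_feature_map(LD); SK <- as_feature_map(SK)
  if (dim(SK)[3] != module$channels) stop("skip-connection channel mismatch")
  if (any(dim(LD)[1:2] * 2L != dim(SK)[1:2]))
    stop("LD must be at half the spatial resolution of SK")
  cca_fw(module$params, module$buffers, "cca", LD, SK, module$config, training)$y
}

# ---- RNG bookkeeping -------------------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
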