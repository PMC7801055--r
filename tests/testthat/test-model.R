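# Architecture: MSFF blocks, CCA fusion, downsampling, initialization,
# forward determinism and gradient flow.

test_that("MSFF splitting bookkeeping telescopes back to the input width", {
  wd <- msff_split_widths(27)
  expect_equal(wd$retained, c(9, 6, 4))
  expect_equal(wd$passed[3], 8)
  expect_equal(wd$concat, 27)
  for (c in c(9, 12, 16, 27, 48, 100))
    expect_equal(msff_split_widths(c)$concat, c)
  expect_error(msff_split_widths(8), "at least 9|>= 9")
})

test_that("MSFF preserves spatial size and maps to the requested width", {
  blk <- msff_block(27, 32, seed = 4)
  x <- array(rnorm(32 * 32 * 27), c(32, 32, 27, 1))
  y <- msff_forward(blk, x)
  expect_equal(dim(y), c(32, 32, 32, 1))
  expect_error(msff_block(8, 16), "9")
  expect_error(msff_forward(blk, array(0, c(32, 32, 9, 1))), "channel")
})

test_that("MSFF receptive field exceeds a plain 3x3 convolution", {
  blk <- msff_block(9, 9, seed = 2)
  # zero biases so the output footprint reflects connectivity only
  for (nm in names(blk$params))
    if (grepl("\\.b$", nm)) blk$params[[nm]][] <- 0
  x <- array(0, c(33, 33, 9, 1)); x[17, 17, , 1] <- 1
  y <- msff_forward(blk, x)
  resp <- apply(abs(y[, , , 1]), 1, max)
  extent <- diff(range(which(resp > 1e-12))) + 1
  expect_gt(extent, 3)   # a plain 3x3 conv spreads a delta to 3 rows
  expect_gte(extent, 9)  # dilated entry + chained 5x5 passes
})

test_that("CCA shapes follow the squeeze ratio and zero inputs gate to zero", {
  mod <- cca_module(channels = 32, channels_ld = 64, reduction_r = 2, seed = 6)
  expect_equal(dim(mod$params[["cca.ld.conv1.w"]]), c(16, 32))
  LD <- array(0, c(8, 8, 64, 1)); SK <- array(0, c(16, 16, 32, 1))
  f <- cca_fuse(mod, LD, SK)
  expect_equal(dim(f), c(16, 16, 64, 1))
  expect_equal(max(abs(f)), 0)  # gated features vanish with zero maps
  expect_error(cca_fuse(mod, array(0, c(8, 8, 64, 1)), array(0, c(20, 16, 32, 1))),
               "half")
})

test_that("CCA with identity weights matches the hand-computed gate", {
  mod <- cca_module(channels = 1, channels_ld = 1, reduction_r = 1, seed = 1)
  P <- mod$params
  P[["cca.proj.w"]] <- array(1, c(1, 1, 1, 1)); P[["cca.proj.b"]] <- 0
  for (path in c("ld", "sk")) {
    P[[paste0("cca.", path, ".conv1.w")]] <- matrix(1, 1, 1)
    P[[paste0("cca.", path, ".conv1.b")]] <- 0
    P[[paste0("cca.", path, ".bn.gamma")]] <- 1
    P[[paste0("cca.", path, ".bn.beta")]] <- 0
    P[[paste0("cca.", path, ".conv2.w")]] <- matrix(1, 1, 1)
    P[[paste0("cca.", path, ".conv2.b")]] <- 0
  }
  mod$params <- P
  a <- 0.3; b <- 0.5
  LD <- array(a, c(2, 2, 1, 1)); SK <- array(b, c(4, 4, 1, 1))
  # evaluation mode: batch norm uses fresh running stats (mean 0, var 1)
  f <- cca_fuse(mod, LD, SK, training = FALSE)
  gate <- a + b  # RReLU is identity for positive sums
  expect_equal(unique(round(as.vector(f[, , 1, 1]), 4)), round(gate * a, 4))
  expect_equal(unique(round(as.vector(f[, , 2, 1]), 4)), round(gate * b, 4))
})

test_that("downsampling halves the spatial dimensions by strided convolution", {
  x <- array(rnorm(64 * 64 * 16), c(64, 64, 16, 1))
  y <- downsample(x, 32, seed = 3)
  expect_equal(dim(y), c(32, 32, 32, 1))
  z <- downsample(array(0, c(16, 16, 4, 2)), 8, bias = FALSE)
  expect_equal(max(abs(z)), 0)
  expect_error(downsample(array(0, c(15, 16, 4, 1)), 8), "even")
})

test_that("builds are reproducible and depth controls the decoder", {
  cfg <- ffunet_config(depth = 2, base_channels = 12)
  m1 <- build_ffunet(cfg, seed = 5)
  m2 <- build_ffunet(cfg, seed = 9)
  expect_identical(count_parameters(m1), count_parameters(m2))
  expect_identical(names(m1$params), names(m2$params))
  cfg4 <- ffunet_config(depth = 4, base_channels = 9)
  m4 <- build_ffunet(cfg4, seed = 1)
  cca_stages <- unique(sub("^(dec[0-9]+)\\.cca\\..*$", "\\1",
                           grep("\\.cca\\.", names(m4$params), value = TRUE)))
  expect_length(cca_stages, 4)
  # parameter count strictly increases with base width
  counts <- vapply(c(9, 12, 16), function(b)
    count_parameters(build_ffunet(ffunet_config(depth = 2, base_channels = b))),
    numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("a lone convolution layer has the hand-counted parameters", {
  p <- fundusseg:::conv_params(3, 3, 3, 16)
  expect_equal(length(p$w) + length(p$b), 3 * 16 * 9 + 16)
})

test_that("He initialization has the defining 2/fan_in weight variance", {
  m <- build_ffunet(ffunet_config(depth = 2, base_channels = 16), seed = 11)
  checked <- 0
  for (nm in grep("\\.w$", names(m$params), value = TRUE)) {
    w <- m$params[[nm]]
    if (length(w) < 1000 || is.null(dim(w)) || length(dim(w)) != 4) next
    fan_in <- prod(dim(w)[1:3])
    expect_lt(abs(var(as.vector(w)) - 2 / fan_in) / (2 / fan_in), 0.2,
              label = nm)
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})

test_that("no pooling operator performs the downsampling", {
  m <- build_ffunet(ffunet_config(depth = 3, base_channels = 9), seed = 1)
  # every resolution change in the encoder is a learned 3x3 kernel
  for (i in 1:3)
    expect_equal(dim(m$params[[paste0("enc", i, ".down.w")]])[1:2], c(3, 3))
  # and no pooling primitive exists in the package's compute vocabulary
  # (global average pooling of the attention vectors is the one exception
  # the architecture prescribes)
  ns <- getNamespaceExports("fundusseg")
  expect_false(any(grepl("max_?pool|avg_?pool", ns, ignore.case = TRUE)))
})

test_that("forward obeys the shape contract and evaluation determinism", {
  cfg <- ffunet_config(depth = 2, base_channels = 9)
  m <- build_ffunet(cfg, seed = 2)
  x <- array(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  q <- ffunet_forward(m, x)
  expect_equal(dim(q), c(64, 64, 1, 2))
  expect_true(all(q > 0 & q < 1))
  expect_identical(q, ffunet_forward(m, x))
  expect_error(ffunet_forward(m, array(0, c(50, 50, 3, 1))), "divisible by 4")
  set.seed(77)  # training mode is stochastic through the RReLU draws
  t1 <- ffunet_forward(m, x, training = TRUE)
  t2 <- ffunet_forward(m, x, training = TRUE)
  expect_false(identical(t1, t2))
})

test_that("every parameter receives a finite gradient that matches finite differences", {
  set.seed(5)
  m <- small_model(depth = 1, base_channels = 9, seed = 3)
  x <- array(rnorm(8 * 8 * 3 * 2, sd = 0.5), c(8, 8, 3, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  fw <- ffunet_forward(m, x, training = FALSE, with_cache = TRUE)
  gq <- fundusseg:::balanced_focal_grad(fw$y, y, w = 0.3, reduction = "mean")
  grads <- fundusseg:::ffunet_backward(m, fw$cache, gq)
  expect_setequal(ls(grads), names(m$params))
  for (nm in ls(grads)) expect_true(all(is.finite(grads[[nm]])), label = nm)
  lossfun <- function(mod) {
    q <- ffunet_forward(mod, x, training = FALSE)
    balanced_focal_loss(q, y, w = 0.3, reduction = "mean")
  }
  set.seed(1); eps <- 1e-5
  for (nm in sample(names(m$params), 12)) {
    p <- m$params[[nm]]
    i <- sample(length(p), 1)
    m2 <- m; m2$params[[nm]][i] <- p[i] + eps
    m3 <- m; m3$params[[nm]][i] <- p[i] - eps
    num <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
    expect_equal(as.numeric(grads[[nm]][i]), num, tolerance = 1e-4,
                 label = sprintf("grad of %s", nm))
  }
})
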