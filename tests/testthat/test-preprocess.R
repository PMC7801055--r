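# ROI detection, denoising, CLAHE, normalization and paired augmentation.

make_disc_image <- function(H = 200, W = 200, cy = 100, cx = 100, r = 50,
                            value = 200) {
  px <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    d <- sqrt(outer((1:H - cy)^2, (1:W - cx)^2, "+"))
    px[, , ch] <- value * (d <= r)
  }
  fundus_image(px)
}

# brute-force Otsu: maximize between-class variance over all 255 cuts;
# ties (flat plateaus between well-separated modes) are averaged
otsu_oracle <- function(lum) {
  counts <- tabulate(floor(lum) + 1L, nbins = 256)
  p <- counts / sum(counts)
  vs <- rep(-Inf, 255)
  for (t in 1:255) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:(t - 1)) * p[1:t]) / w0
    mu1 <- sum((t:255) * p[(t + 1):256]) / w1
    vs[t] <- w0 * w1 * (mu0 - mu1)^2
  }
  mean(which(vs >= max(vs) - 1e-12))
}

test_that("find_roi recovers a centered disc, cross-checked against brute-force Otsu", {
  img <- make_disc_image()
  roi <- find_roi(img)
  b <- roi$box
  expect_lte(abs(b$row_start - 50), 2); expect_lte(abs(b$row_end - 151), 2)
  expect_lte(abs(b$col_start - 50), 2); expect_lte(abs(b$col_end - 151), 2)
  # cropping loses no ROI pixel
  expect_equal(sum(roi$roi_mask), sum(crop_raster(roi$roi_mask, b)))
  # the resulting foreground agrees with an exhaustive
  # between-class-variance search (thresholds differ only within the flat
  # plateau between the two modes, where the split is identical)
  set.seed(61)
  noisy <- img
  noisy$pixels <- pmin(pmax(img$pixels +
                              array(rnorm(length(img$pixels), 0, 12),
                                    dim(img$pixels)), 0), 255)
  lum <- 0.299 * noisy$pixels[, , 1] + 0.587 * noisy$pixels[, , 2] +
    0.114 * noisy$pixels[, , 3]
  thr_pkg <- EBImage::otsu(lum / 255, range = c(0, 1), levels = 256) * 255
  fg_pkg <- lum > thr_pkg
  fg_oracle <- lum > otsu_oracle(lum)
  expect_gt(mean(fg_pkg == fg_oracle), 0.999)
})

test_that("find_roi keeps only the largest component and rejects flat images", {
  px <- array(0, c(100, 100, 3))
  px[10:40, 10:30, ] <- 220   # area 651
  px[70:77, 70:79, ] <- 220   # area 80
  roi <- find_roi(fundus_image(px))
  expect_equal(c(roi$box$row_start, roi$box$row_end), c(9, 40))
  expect_equal(c(roi$box$col_start, roi$box$col_end), c(9, 30))
  # image entirely bright -> full frame
  full <- find_roi(fundus_image(array(200, c(50, 60, 3)) +
                                  array(runif(50 * 60 * 3), c(50, 60, 3))))
  expect_equal(c(full$box$row_end, full$box$col_end), c(50, 60))
  expect_error(find_roi(fundus_image(array(7, c(20, 20, 3)))), "degenerate")
})

test_that("find_roi is idempotent after cropping", {
  out <- generate_fundus(tile_synth_config(seed = 12, size = 128))
  roi1 <- find_roi(out$image)
  cropped <- crop_raster(out$image, roi1$box)
  roi2 <- find_roi(cropped)
  d <- dim(cropped$pixels)
  expect_lte(roi2$box$row_start, 2)
  expect_gte(roi2$box$row_end, d[1] - 2)
  expect_lte(roi2$box$col_start, 2)
  expect_gte(roi2$box$col_end, d[2] - 2)
})

test_that("Gaussian denoising matches hand convolution and shrinks variance", {
  const <- fundus_image(array(120, c(30, 30, 3)))
  expect_equal(denoise(const)$pixels, const$pixels, tolerance = 1e-10)
  # single bright pixel: center value = kernel center weight * 255
  px <- array(0, c(21, 21, 3)); px[11, 11, ] <- 255
  k <- EBImage::makeBrush(3, "gaussian", sigma = 0.8)
  sm <- denoise(fundus_image(px))
  expect_equal(sm$pixels[11, 11, 1], 255 * k[2, 2], tolerance = 1e-8)
  expect_equal(sm$pixels[10, 11, 1], 255 * k[1, 2], tolerance = 1e-8)
  set.seed(30)
  noisy <- fundus_image(array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3)))
  den <- denoise(noisy)
  for (ch in 1:3)
    expect_lt(var(as.vector(den$pixels[, , ch])),
              var(as.vector(noisy$pixels[, , ch])))
})

test_that("CLAHE raises contrast of low-contrast images deterministically", {
  set.seed(41)
  ramp <- array(rep(seq(100, 130, length.out = 120), each = 120), c(120, 120, 1))
  px <- array(rep(ramp, 3), c(120, 120, 3)) + array(rnorm(120^2 * 3), c(120, 120, 3))
  img <- fundus_image(pmin(pmax(px, 0), 255))
  enh <- enhance_contrast(img)
  lum_in <- apply(img$pixels, c(1, 2), mean)
  lum_out <- apply(enh$pixels, c(1, 2), mean)
  expect_gt(sd(lum_out), sd(lum_in))
  expect_equal(dim(enh$pixels), dim(img$pixels))
  expect_true(all(enh$pixels >= 0 & enh$pixels <= 255))
  expect_identical(enhance_contrast(img)$pixels, enh$pixels)
  flat <- fundus_image(array(90, c(40, 40, 3)))
  expect_equal(enhance_contrast(flat)$pixels, flat$pixels)
})

test_that("dataset statistics equal the concatenate-then-moments oracle", {
  one <- fundus_image(array(c(0, 2), c(1, 1, 3))[, , c(1, 1, 1), drop = FALSE])
  expect_error(compute_dataset_stats(list(fundus_image(array(100, c(2, 2, 3))))),
               "zero variance")
  two <- list(fundus_image(array(0, c(1, 1, 3))), fundus_image(array(2, c(1, 1, 3))))
  st <- compute_dataset_stats(two)
  expect_equal(st$mean, rep(1, 3))
  expect_equal(st$std, rep(1, 3))
  imgs <- lapply(1:10, function(s) generate_fundus(tile_synth_config(seed = s))$image)
  st <- compute_dataset_stats(imgs)
  for (ch in 1:3) {
    all_px <- unlist(lapply(imgs, function(im) as.vector(im$pixels[, , ch])))
    expect_equal(st$mean[ch], mean(all_px), tolerance = 1e-10)
    expect_equal(st$std[ch], sqrt(mean((all_px - mean(all_px))^2)),
                 tolerance = 1e-10)
  }
})

test_that("normalization follows (x - mu) / theta and inverts exactly", {
  st <- structure(list(mean = c(50, 50, 50), std = c(10, 10, 10)),
                  class = "norm_stats")
  img <- fundus_image(array(c(50, 60, 30), c(1, 3, 1))[, , c(1, 1, 1), drop = FALSE])
  px <- array(0, c(2, 2, 3)); px[, , ] <- c(50, 60, 30, 70)
  nm <- normalize_image(fundus_image(px), st)
  expect_equal(nm$value_range, "normalized")
  expect_equal(nm$pixels[1, 1, 1], 0)
  expect_equal(nm$pixels[2, 1, 1], 1)
  expect_equal(nm$pixels[1, 2, 1], -2)
  back <- denormalize_image(nm, st)
  expect_equal(back$pixels, px, tolerance = 1e-6)
  st$std <- c(0, 1, 1)
  expect_error(normalize_image(fundus_image(px), st), "positive")
})

test_that("augmentation transforms image and mask identically", {
  out <- generate_fundus(tile_synth_config(seed = 19))
  # identity parameters return the input unchanged
  id <- augment(out$image, out$mask, seed = 1, flip_prob = 0, max_rotate = 0,
                max_shift = 0, scale_range = c(1, 1))
  expect_equal(id$image$pixels, out$image$pixels)
  expect_identical(id$mask$pixels, out$mask$pixels)
  # pure flip: lesion at column c moves to W - 1 - c in both
  fl <- augment(out$image, out$mask, seed = 1, flip_prob = 1, max_rotate = 0,
                max_shift = 0, scale_range = c(1, 1))
  W <- ncol(out$mask$pixels)
  expect_identical(fl$mask$pixels, out$mask$pixels[, W:1])
  expect_equal(fl$image$pixels[, , 2], out$image$pixels[, W:1, 2])
  # same seed reproduces the full random transform
  a1 <- augment(out$image, out$mask, seed = 33)
  a2 <- augment(out$image, out$mask, seed = 33)
  expect_identical(a1$image$pixels, a2$image$pixels)
  expect_identical(a1$mask$pixels, a2$mask$pixels)
  expect_true(all(a1$mask$pixels %in% c(0L, 1L)))
  expect_error(augment(out$image, lesion_mask(matrix(0L, 3, 3))), "aligned")
})

test_that("alignment survives a random rotation+scale+shift", {
  out <- generate_fundus(tile_synth_config(seed = 23))
  a <- augment(out$image, out$mask, seed = 101, flip_prob = 0.5)
  # lesion pixels in the transformed mask sit on transformed lesion intensity:
  # EX lesions are bright in red channel relative to local background
  pos <- which(a$mask$pixels == 1, arr.ind = TRUE)
  if (nrow(pos) > 10) {
    les_mean <- mean(a$image$pixels[, , 1][a$mask$pixels == 1])
    bg_mean <- mean(a$image$pixels[, , 1][a$mask$pixels == 0 &
                                            a$image$pixels[, , 1] > 0])
    expect_gt(les_mean, bg_mean)
  }
})
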