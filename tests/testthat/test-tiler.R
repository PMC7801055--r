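# Sliding-window dicing, background elimination, coverage and merging.

test_that("grid enumeration covers the image with edge-flush offsets", {
  g <- tile_grid(512, 512, 256, 64)
  expect_equal(nrow(g$offsets), 25)  # (512-256)/64+1 = 5 per axis
  g1 <- tile_grid(256, 256, 256, 64)
  expect_equal(nrow(g1$offsets), 1)
  # 300x300: offsets {0, 44} per axis, 4 tiles, full coverage
  g2 <- tile_grid(300, 300, 256, 64)
  expect_equal(sort(unique(g2$offsets[, "row"])), c(0L, 44L))
  expect_equal(nrow(g2$offsets), 4)
  cov <- matrix(0L, 300, 300)
  for (i in seq_len(nrow(g2$offsets))) {
    r <- g2$offsets[i, "row"]; c <- g2$offsets[i, "col"]
    cov[r + 1:256, c + 1:256] <- cov[r + 1:256, c + 1:256] + 1L
  }
  expect_true(all(cov >= 1))
  expect_error(tile_grid(200, 200, 256, 64), "smaller than window")
  expect_error(tile_grid(300, 300, 256, 0), "stride")
})

test_that("dicing cuts tiles at every offset and round-trips through merge", {
  set.seed(5)
  img <- matrix(runif(300 * 300), 300)
  d <- dice_image(img, 256, 64)
  expect_equal(length(d$tiles), nrow(d$grid$offsets))
  i <- 3
  r <- d$grid$offsets[i, "row"]; c <- d$grid$offsets[i, "col"]
  expect_equal(d$tiles[[i]], img[r + 1:256, c + 1:256])
  # identity "predictor": merge reconstructs the image exactly
  rec <- merge_tiles(d$tiles, d$grid)
  expect_equal(rec, img, tolerance = 1e-12)
})

test_that("background filtering matches a per-tile ROI counting oracle", {
  g <- tile_grid(512, 512, 256, 64)
  expect_true(all(filter_background(g, matrix(1, 512, 512))$valid_flags))
  expect_false(any(filter_background(g, matrix(0, 512, 512))$valid_flags))
  # disc-shaped ROI
  dist <- sqrt(outer((1:512 - 256.5)^2, (1:512 - 256.5)^2, "+"))
  roi <- (dist <= 200) * 1
  gf <- filter_background(g, roi, min_roi_fraction = 0.5)
  oracle <- vapply(seq_len(nrow(g$offsets)), function(i) {
    r <- g$offsets[i, "row"]; c <- g$offsets[i, "col"]
    mean(roi[r + 1:256, c + 1:256]) >= 0.5
  }, logical(1))
  expect_equal(gf$valid_flags, oracle)
  # flags already cleared stay cleared
  g$valid_flags[1] <- FALSE
  expect_false(filter_background(g, matrix(1, 512, 512))$valid_flags[1])
})

test_that("coverage counts follow the window/stride geometry", {
  g <- tile_grid(1024, 1024, 256, 64)
  expect_equal(coverage_count(g, c(512, 512)), 16)  # interior: 4 per axis
  expect_equal(coverage_count(g, c(0, 0)), 1)
  gnov <- tile_grid(512, 512, 256, 256)
  for (p in list(c(0, 0), c(255, 255), c(256, 256), c(511, 511)))
    expect_equal(coverage_count(gnov, p), 1)
  expect_error(coverage_count(g, c(1024, 0)), "out of bounds")
  # conservation: sum of coverage over pixels = n_valid * window^2
  g3 <- tile_grid(300, 300, 128, 96)
  total <- sum(vapply(0:299, function(r)
    sum(vapply(0:299, function(c) coverage_count(g3, c(r, c)), numeric(1))),
    numeric(1)))
  expect_equal(total, nrow(g3$offsets) * 128^2)
})

test_that("merge averages overlapping predictions per pixel", {
  g <- tile_grid(320, 320, 256, 64)
  const <- lapply(seq_len(nrow(g$offsets)), function(i) matrix(0.7, 256, 256))
  m <- merge_tiles(const, g)
  expect_true(all(abs(m - 0.7) < 1e-15))
  # two overlapping tiles, 0 and 1 -> 0.5 in the overlap
  g2 <- tile_grid(256, 320, 256, 64)
  expect_equal(nrow(g2$offsets), 2)
  m2 <- merge_tiles(list(matrix(0, 256, 256), matrix(1, 256, 256)), g2)
  expect_equal(unique(as.vector(m2[, 65:256])), 0.5)
  expect_equal(unique(as.vector(m2[, 1:64])), 0)
  expect_equal(unique(as.vector(m2[, 257:320])), 1)
})

test_that("merge equals a brute-force accumulator and ignores tile order", {
  set.seed(8)
  g <- tile_grid(512, 512, 256, 64)
  g$valid_flags[sample(nrow(g$offsets), 5)] <- FALSE
  preds <- lapply(seq_len(nrow(g$offsets)), function(i) matrix(runif(256^2), 256))
  m <- merge_tiles(preds, g)
  acc <- matrix(0, 512, 512); cnt <- matrix(0, 512, 512)
  for (i in which(g$valid_flags)) {
    r <- g$offsets[i, "row"]; c <- g$offsets[i, "col"]
    acc[r + 1:256, c + 1:256] <- acc[r + 1:256, c + 1:256] + preds[[i]]
    cnt[r + 1:256, c + 1:256] <- cnt[r + 1:256, c + 1:256] + 1
  }
  brute <- acc / cnt; brute[cnt == 0] <- NA
  expect_equal(m, brute, tolerance = 1e-12)
  # uncovered pixels are NA sentinels
  g0 <- tile_grid(320, 320, 128, 128)
  g0$valid_flags[] <- FALSE; g0$valid_flags[1] <- TRUE
  m0 <- merge_tiles(list(matrix(0.5, 128, 128)), g0)
  expect_true(all(is.na(m0[200:320, 200:320])))
  expect_error(merge_tiles(list(matrix(0.5, 64, 64)), g0), "shape")
})

test_that("tile grids survive a JSON round trip", {
  g <- tile_grid(300, 280, 128, 96)
  g$valid_flags[3] <- FALSE
  path <- withr::local_tempfile(fileext = ".json")
  tile_grid_to_json(g, path)
  g2 <- tile_grid_from_json(path)
  expect_equal(g2$offsets, g$offsets)
  expect_equal(g2$valid_flags, g$valid_flags)
})
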