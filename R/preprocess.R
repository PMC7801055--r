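# Fundus preprocessing: (1) ROI cropping by Otsu thresholding of the
# luminance and the largest 8-connected foreground component, (2) Gaussian
# 3x3 denoising, (3) CLAHE contrast enhancement on the L channel of LAB,
# (4) dataset mean/std normalization, (5) paired geometric augmentation.

luminance <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

#' Locate the region of interest (camera field of view)
#'
#' Otsu's threshold is applied to the luminance channel; the largest
#' 8-connected above-threshold component is taken as the field of view. The
#' returned bounding box is the tight box of that component, so cropping
#' with it loses no ROI pixel.
#'
#' @param image A [fundus_image()] with intensities 0..255.
#' @return List with `box` (a [bounding_box()]) and `roi_mask` (binary
#'   `H x W` matrix of the largest component).
#' @export
find_roi <- function(image) {
  stopifnot(inherits(image, "fundus_image"))
  lum <- luminance(image$pixels)
  if (stats::var(as.vector(lum)) == 0)
    stop("degenerate input: constant image has no foreground/background split")
  thr <- EBImage::otsu(lum / 255, range = c(0, 1), levels = 256)
  fg <- (lum / 255 > thr) * 1L
  if (!any(fg == 1)) stop("degenerate input: no foreground above Otsu threshold")
  lab <- cpp_label_components(matrix(as.integer(fg), nrow(fg), ncol(fg)))
  sizes <- tabulate(lab[lab > 0])
  comp <- (lab == which.max(sizes)) * 1L
  rows <- range(which(rowSums(comp) > 0))
  cols <- range(which(colSums(comp) > 0))
  list(box = bounding_box(rows[1] - 1L, rows[2], cols[1] - 1L, cols[2]),
       roi_mask = comp)
}

#' Gaussian 3x3 denoising
#'
#' Convolves each channel with a 3x3 Gaussian kernel (sigma 0.8 by default,
#' a standard choice for a 3-tap Gaussian), replicating edge pixels at the
#' boundary.
#'
#' @param image A [fundus_image()] with intensities 0..255.
#' @param sigma Kernel standard deviation in pixels.
#' @return The smoothed `fundus_image`.
#' @export
denoise <- function(image, sigma = 0.8) {
  stopifnot(inherits(image, "fundus_image"))
  if (image$value_range != "uint8") stop("denoise expects 0..255 intensities")
  k <- EBImage::makeBrush(3, shape = "gaussian", sigma = sigma)
  out <- image$pixels
  for (ch in 1:3)
    out[, , ch] <- as.matrix(EBImage::filter2(image$pixels[, , ch], k,
                                              boundary = "replicate"))
  fundus_image(out, "uint8", image$roi_mask)
}

#' CLAHE contrast enhancement
#'
#' Contrast-limited adaptive histogram equalization applied to the L channel
#' of LAB color space (clip limit 2, 8 x 8 tile grid by default), leaving
#' chroma untouched. The image is edge-padded to a tile-grid multiple and
#' cropped back.
#'
#' @param image A [fundus_image()] with intensities 0..255.
#' @param clip_limit CLAHE clip limit.
#' @param grid Number of contextual tiles per axis.
#' @return The enhanced `fundus_image`, same shape and range.
#' @export
enhance_contrast <- function(image, clip_limit = 2, grid = 8L) {
  stopifnot(inherits(image, "fundus_image"))
  if (image$value_range != "uint8") stop("CLAHE expects 0..255 intensities")
  d <- dim(image$pixels)
  rgb <- matrix(image$pixels / 255, ncol = 3L)
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  if (stats::sd(lab[, 1]) == 0) return(image)  # flat histogram: no-op
  L <- matrix(lab[, 1] / 100, d[1], d[2])
  Hp <- ceiling(d[1] / grid) * grid
  Wp <- ceiling(d[2] / grid) * grid
  Lp <- L[c(seq_len(d[1]), rep(d[1], Hp - d[1])),
          c(seq_len(d[2]), rep(d[2], Wp - d[2])), drop = FALSE]
  Le <- as.matrix(EBImage::clahe(Lp, nx = grid, ny = grid, limit = clip_limit))
  lab[, 1] <- pmin(pmax(as.vector(Le[seq_len(d[1]), seq_len(d[2])]), 0), 1) * 100
  out <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  out <- array(pmin(pmax(out, 0), 1) * 255, d)
  fundus_image(out, "uint8", image$roi_mask)
}

#' Per-channel normalization statistics over a dataset
#'
#' Pooled mean and standard deviation of every pixel of every image, per
#' channel, computed in a single pass. Statistics are meant to be computed
#' on the training split and reused at test time.
#'
#' @param images List of [fundus_image()] objects (0..255 intensities).
#' @return A `norm_stats` list with numeric `mean` and `std` of length 3.
#' @export
compute_dataset_stats <- function(images) {
  if (length(images) < 1) stop("need at least one image")
  s <- numeric(3); s2 <- numeric(3); n <- 0
  for (im in images) {
    stopifnot(inherits(im, "fundus_image"))
    px <- im$pixels
    m <- matrix(px, ncol = 3L)
    s <- s + colSums(m)
    s2 <- s2 + colSums(m^2)
    n <- n + nrow(m)
  }
  mu <- s / n
  va <- s2 / n - mu^2
  va[va < 0] <- 0
  if (any(va == 0)) stop("degenerate input: zero variance in some channel")
  structure(list(mean = mu, std = sqrt(va)), class = "norm_stats")
}

#' Normalize an image with dataset statistics
#'
#' `x_norm = (x - mu) / theta` per channel.
#'
#' @param image A [fundus_image()].
#' @param stats A `norm_stats` object from [compute_dataset_stats()].
#' @return A `fundus_image` with `value_range = "normalized"`.
#' @export
normalize_image <- function(image, stats) {
  stopifnot(inherits(image, "fundus_image"), inherits(stats, "norm_stats"))
  if (any(stats$std <= 0)) stop("normalization std must be strictly positive")
  out <- image$pixels
  for (ch in 1:3) out[, , ch] <- (out[, , ch] - stats$mean[ch]) / stats$std[ch]
  fundus_image(out, "normalized", image$roi_mask)
}

#' Invert [normalize_image()]
#'
#' @inheritParams normalize_image
#' @return A `fundus_image` back on the 0..255 scale.
#' @export
denormalize_image <- function(image, stats) {
  stopifnot(inherits(image, "fundus_image"), inherits(stats, "norm_stats"))
  out <- image$pixels
  for (ch in 1:3) out[, , ch] <- out[, , ch] * stats$std[ch] + stats$mean[ch]
  fundus_image(out, "uint8", image$roi_mask)
}

#' Paired geometric augmentation
#'
#' Applies one random geometric transform -- horizontal flip, rotation,
#' isotropic rescaling and shift -- identically to an image and its mask.
#' The image is resampled bilinearly, the mask with nearest-neighbour
#' interpolation so it stays binary. A fixed seed reproduces the transform;
#' setting all ranges to their identity values returns the inputs unchanged.
#'
#' @param image A [fundus_image()].
#' @param mask The aligned [lesion_mask()].
#' @param seed Integer seed for the random draws.
#' @param flip_prob Probability of a horizontal flip.
#' @param max_rotate Maximum absolute rotation, degrees.
#' @param max_shift Maximum absolute shift as a fraction of each dimension.
#' @param scale_range Interval of isotropic rescale factors.
#' @return List `(image, mask)` with unchanged shapes.
#' @export
augment <- function(image, mask, seed = 1L, flip_prob = 0.5, max_rotate = 15,
                    max_shift = 0.1, scale_range = c(0.9, 1.1)) {
  stopifnot(inherits(image, "fundus_image"), inherits(mask, "lesion_mask"))
  d <- dim(image$pixels)
  if (!identical(dim(mask$pixels), d[1:2]))
    stop("image and mask are not spatially aligned")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  do_flip <- stats::runif(1) < flip_prob
  ang <- if (max_rotate > 0) stats::runif(1, -max_rotate, max_rotate) else 0
  sc <- if (diff(range(scale_range)) > 0 || any(scale_range != 1))
    stats::runif(1, scale_range[1], scale_range[2]) else 1
  sh <- if (max_shift > 0) round(stats::runif(2, -max_shift, max_shift) * d[1:2]) else c(0, 0)

  tf_one <- function(px, bilinear) {
    filt <- if (bilinear) "bilinear" else "none"
    x <- px
    if (do_flip) {
      if (length(dim(x)) == 3L) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
      else x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
    }
    if (ang != 0)
      x <- as.array(EBImage::rotate(x, ang, filter = filt,
                                    output.dim = c(d[1], d[2]), bg.col = 0))
    if (sc != 1) {
      hs <- max(1L, round(d[1] * sc)); ws <- max(1L, round(d[2] * sc))
      x <- as.array(EBImage::resize(x, w = hs, h = ws, filter = filt))
      x <- fit_canvas(x, d[1], d[2])
    }
    if (any(sh != 0))
      x <- as.array(EBImage::translate(x, c(sh[1], sh[2]), filter = "none", bg.col = 0))
    x
  }
  out_img <- tf_one(image$pixels, bilinear = TRUE)
  out_msk <- tf_one(mask$pixels, bilinear = FALSE)
  dim(out_img) <- d
  out_msk <- matrix((out_msk > 0.5) * 1L, d[1], d[2])
  list(image = fundus_image(pmin(pmax(out_img, 0), 255),
                            image$value_range),
       mask = lesion_mask(out_msk, mask$lesion_class))
}

# centre-crop or zero-pad a raster to H x W
fit_canvas <- function(x, H, W) {
  d3 <- length(dim(x)) == 3L
  h <- dim(x)[1]; w <- dim(x)[2]
  if (h >= H) {
    off <- (h - H) %/% 2
    x <- if (d3) x[off + seq_len(H), , , drop = FALSE] else x[off + seq_len(H), , drop = FALSE]
  }
  if (w >= W) {
    off <- (dim(x)[2] - W) %/% 2
    x <- if (d3) x[, off + seq_len(W), , drop = FALSE] else x[, off + seq_len(W), drop = FALSE]
  }
  h <- dim(x)[1]; w <- dim(x)[2]
  if (h < H || w < W) {
    out <- if (d3) array(0, c(H, W, dim(x)[3])) else matrix(0, H, W)
    ro <- (H - h) %/% 2; co <- (W - w) %/% 2
    if (d3) out[ro + seq_len(h), co + seq_len(w), ] <- x
    else out[ro + seq_len(h), co + seq_len(w)] <- x
    x <- out
  }
  x
}

#' Full preprocessing of one image
#'
#' Crop to the ROI, denoise, enhance contrast, and (optionally) normalize,
#' in that order.
#'
#' @param image A [fundus_image()] with intensities 0..255.
#' @param stats Optional `norm_stats`; when given the result is normalized.
#' @param mask Optional aligned [lesion_mask()], cropped identically.
#' @return List with `image`, `roi_mask` (cropped), `box`, and `mask`
#'   (cropped, or `NULL`).
#' @export
preprocess_fundus <- function(image, stats = NULL, mask = NULL) {
  roi <- find_roi(image)
  img <- crop_raster(image, roi$box)
  img$roi_mask <- crop_raster(roi$roi_mask, roi$box)
  img <- enhance_contrast(denoise(img))
  if (!is.null(stats)) img <- normalize_image(img, stats)
  out_mask <- if (is.null(mask)) NULL else crop_raster(mask, roi$box)
  list(image = img, roi_mask = img$roi_mask, box = roi$box, mask = out_mask)
}
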