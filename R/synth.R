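# Deterministic synthetic fundus generator.
#
# Emulates the statistical structure the segmentation pipeline assumes: a
# bright roughly circular field of view on a black border, dark curvilinear
# vessel-like structures, and lesions of four classes at very different
# spatial scales -- microaneurysms (MA) as tiny dark dots, hard exudates
# (EX) as bright compact blobs, soft exudates (SE) as pale fuzzy blobs, and
# hemorrhages (HE) as dark irregular (elliptical) patches -- each paired
# with a pixel-accurate binary mask.  It makes no attempt at photorealism:
# no optic disc, fovea, or camera optics.

lesion_defaults <- list(
  MA = list(radius = c(1.5, 3), offset = -45, count = c(10L, 25L), soft = 0.5),
  EX = list(radius = c(8, 20), offset = +70, count = c(3L, 8L), soft = 0.5),
  SE = list(radius = c(10, 24), offset = +45, count = c(2L, 5L), soft = NA),
  HE = list(radius = c(8, 24), offset = -50, count = c(2L, 6L), soft = 0.5)
)

#' Synthetic fundus configuration
#'
#' Defaults follow the scales of the four diabetic-retinopathy lesion
#' classes: microaneurysm radii are an order of magnitude below exudate and
#' hemorrhage radii, exudates are brighter than the fundus background and
#' microaneurysms/hemorrhages darker. The default canvas is 512 x 512 for
#' speed; full-camera resolutions are available through
#' `image_height`/`image_width`.
#'
#' @param image_height,image_width Canvas size in pixels.
#' @param disc_radius_fraction Field-of-view radius as a fraction of
#'   `min(H, W)`; must lie in (0, 0.5].
#' @param vessel_count Number of vessel-like curvilinear structures.
#' @param lesion_class One of `"MA"`, `"EX"`, `"SE"`, `"HE"`.
#' @param lesion_count_range Integer interval for the number of lesions;
#'   `c(0, 0)` generates a negative sample (empty mask).
#' @param lesion_radius_range Pixel interval for lesion radii; defaults per
#'   class.
#' @param lesion_intensity_offset Signed intensity delta stamped on the
#'   image (bright for EX/SE, dark for MA/HE); defaults per class.
#' @param noise_sigma Standard deviation of Gaussian pixel noise added after
#'   lesion stamping (0..255 intensity units).
#' @param seed Integer seed; identical configurations (including the seed)
#'   reproduce byte-identical outputs.
#' @return A `synth_config` list.
#' @export
synth_config <- function(image_height = 512L, image_width = 512L,
                         disc_radius_fraction = 0.45, vessel_count = 6L,
                         lesion_class = c("EX", "MA", "SE", "HE"),
                         lesion_count_range = NULL,
                         lesion_radius_range = NULL,
                         lesion_intensity_offset = NULL,
                         noise_sigma = 5, seed = 1L) {
  lesion_class <- match.arg(lesion_class)
  def <- lesion_defaults[[lesion_class]]
  if (is.null(lesion_count_range)) lesion_count_range <- def$count
  if (is.null(lesion_radius_range)) lesion_radius_range <- def$radius
  if (is.null(lesion_intensity_offset)) lesion_intensity_offset <- def$offset
  if (image_height < 16L || image_width < 16L)
    stop("image dimensions must be at least 16 pixels")
  if (!(disc_radius_fraction > 0 && disc_radius_fraction <= 0.5))
    stop("disc_radius_fraction must lie in (0, 0.5]")
  if (length(lesion_radius_range) != 2L || any(lesion_radius_range <= 0) ||
      lesion_radius_range[1] > lesion_radius_range[2])
    stop("lesion_radius_range must be a nonempty positive interval")
  if (length(lesion_count_range) != 2L || any(lesion_count_range < 0) ||
      lesion_count_range[1] > lesion_count_range[2])
    stop("lesion_count_range must be a nonempty nonnegative interval")
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 disc_radius_fraction = disc_radius_fraction,
                 vessel_count = as.integer(vessel_count),
                 lesion_class = lesion_class,
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 lesion_intensity_offset = lesion_intensity_offset,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic fundus image and lesion mask
#'
#' @param config A [synth_config()].
#' @return List with `image` (a [fundus_image()] carrying the field-of-view
#'   disc as `roi_mask`), `mask` (a [lesion_mask()]), and `lesions` (a data
#'   frame of stamped lesion centres, radii and orientations, usable as an
#'   independent record of the ground truth).
#' @export
generate_fundus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)

  H <- config$image_height; W <- config$image_width
  radius <- config$disc_radius_fraction * min(H, W)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rowd <- matrix(seq_len(H) - cy, H, W)
  cold <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  dist <- sqrt(rowd^2 + cold^2)
  disc_alpha <- pmin(pmax(radius + 0.5 - dist, 0), 1)
  roi <- (dist <= radius) * 1

  # base fundus coloring with a mild radial vignette
  shade <- pmin((dist / radius)^2, 1)
  img <- array(0, c(H, W, 3))
  img[, , 1] <- (190 - 55 * shade) * disc_alpha
  img[, , 2] <- (95 - 30 * shade) * disc_alpha
  img[, , 3] <- (45 - 15 * shade) * disc_alpha

  # vessel-like curvilinear structures: smooth arcs from near the centre,
  # darkening the base color along a 2-3 px wide track
  vessel <- matrix(0, H, W)
  for (v in seq_len(config$vessel_count)) {
    a0 <- stats::runif(1, 0, 2 * pi)
    curv <- stats::runif(1, -0.8, 0.8)
    width <- sample(1:2, 1)
    len <- radius * stats::runif(1, 1.0, 1.5)
    ts <- seq(0.05, 1, by = 0.7 / len)
    ang <- a0 + curv * sin(2.2 * ts)
    pr <- cy + cumsum(c(0, diff(ts)) * len * sin(ang)) + radius * 0.1 * sin(a0)
    pc <- cx + cumsum(c(0, diff(ts)) * len * cos(ang)) + radius * 0.1 * cos(a0)
    for (s in seq_along(ts)) {
      r0 <- round(pr[s]); c0 <- round(pc[s])
      for (dr in -width:width) for (dc in -width:width) {
        rr <- r0 + dr; cc <- c0 + dc
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            dr * dr + dc * dc <= width * width)
          vessel[rr, cc] <- 1
      }
    }
  }
  vessel <- vessel * roi
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.45 * vessel)

  # lesions: anti-aliased discs (ellipses for HE) with class-dependent
  # intensity offsets; placed fully inside the field of view, non-overlapping
  cr <- config$lesion_count_range
  n_les <- if (cr[2] == 0L) 0L else if (cr[1] == cr[2]) cr[1] else
    sample(seq(cr[1], cr[2]), 1)
  mask <- matrix(0L, H, W)
  lesions <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0),
                        axis2 = numeric(0), angle = numeric(0))
  tries <- 0L
  while (nrow(lesions) < n_les && tries < 200L * n_les) {
    tries <- tries + 1L
    r <- stats::runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
    ax2 <- if (config$lesion_class == "HE") r * stats::runif(1, 0.45, 0.95) else r
    th <- if (config$lesion_class == "HE") stats::runif(1, 0, pi) else 0
    rpos <- stats::runif(1, 0, radius - r - 2)
    apos <- stats::runif(1, 0, 2 * pi)
    lr <- cy + rpos * sin(apos); lc <- cx + rpos * cos(apos)
    if (nrow(lesions) > 0) {
      sep <- sqrt((lesions$row - lr)^2 + (lesions$col - lc)^2)
      if (any(sep < lesions$radius + r + 2)) next
    }
    lesions[nrow(lesions) + 1L, ] <- c(lr, lc, r, ax2, th)
  }

  soft <- lesion_defaults[[config$lesion_class]]$soft
  for (k in seq_len(nrow(lesions))) {
    alpha <- stamp_alpha(H, W, lesions$row[k], lesions$col[k], lesions$radius[k],
                         lesions$axis2[k], lesions$angle[k],
                         if (is.na(soft)) 0.35 * lesions$radius[k] else soft)
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] + config$lesion_intensity_offset * alpha
    mask[alpha >= 0.5] <- 1L
  }
  mask <- mask * (roi == 1)

  if (config$noise_sigma > 0)
    img <- img + array(stats::rnorm(length(img), 0, config$noise_sigma), dim(img))
  img <- round(pmin(pmax(img, 0), 255))

  list(image = fundus_image(img, "uint8", roi_mask = roi),
       mask = lesion_mask(mask, config$lesion_class),
       lesions = lesions)
}

# anti-aliased (soft-edged) elliptical footprint; alpha in [0,1],
# alpha >= 0.5 exactly where the elliptical distance is <= the radius
stamp_alpha <- function(H, W, cr, cc, r, ax2, angle, soft) {
  r1 <- max(1L, floor(cr - r - soft - 1)); r2 <- min(H, ceiling(cr + r + soft + 1))
  c1 <- max(1L, floor(cc - r - soft - 1)); c2 <- min(W, ceiling(cc + r + soft + 1))
  alpha <- matrix(0, H, W)
  rows <- r1:r2; cols <- c1:c2
  dr <- matrix(rows - cr, length(rows), length(cols))
  dc <- matrix(cols - cc, length(rows), length(cols), byrow = TRUE)
  u <- dr * cos(angle) + dc * sin(angle)
  v <- -dr * sin(angle) + dc * cos(angle)
  ed <- r * sqrt((u / r)^2 + (v / ax2)^2)  # elliptical distance in radius units
  soft <- max(soft, 1e-6)
  alpha[rows, cols] <- pmin(pmax((r - ed) / (2 * soft) + 0.5, 0), 1)
  alpha
}

#' Generate a dataset of synthetic image/mask pairs
#'
#' Items use per-item seeds derived from the base configuration's seed, so a
#' fixed base seed reproduces the full dataset. A stated fraction of items
#' are negatives (no lesions, empty mask).
#'
#' @param n Number of pairs (>= 1).
#' @param base_config A [synth_config()] used as template.
#' @param negative_fraction Fraction of items generated with
#'   `lesion_count_range = c(0, 0)`; `round(n * negative_fraction)` items.
#' @return List of `n` elements as returned by [generate_fundus()].
#' @export
generate_dataset <- function(n, base_config, negative_fraction = 0.25) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  stopifnot(inherits(base_config, "synth_config"))
  if (!(negative_fraction >= 0 && negative_fraction <= 1))
    stop("negative_fraction must lie in [0, 1]")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(base_config$seed)
  n_neg <- round(n * negative_fraction)
  neg_idx <- if (n_neg > 0) sample(n, n_neg) else integer(0)
  lapply(seq_len(n), function(i) {
    cfg <- base_config
    cfg$seed <- as.integer((base_config$seed + 7919 * i) %% .Machine$integer.max)
    if (i %in% neg_idx) cfg$lesion_count_range <- c(0L, 0L)
    generate_fundus(cfg)
  })
}

#' Write a fundus image as an 8-bit RGB PNG
#'
#' @param image A `fundus_image` with `value_range = "uint8"`.
#' @param path Output file.
#' @export
write_fundus_png <- function(image, path) {
  stopifnot(inherits(image, "fundus_image"))
  if (image$value_range != "uint8") stop("write the image before normalization")
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Write a lesion mask as a single-channel PNG with values \{0, 255\}
#'
#' @param mask A `lesion_mask`.
#' @param path Output file.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  px <- mask$pixels
  storage.mode(px) <- "double"
  png::writePNG(px, path)
  invisible(path)
}

#' Read a fundus image from PNG or JPG
#'
#' @param path Image file.
#' @return A `fundus_image` with intensities 0..255.
#' @export
read_fundus <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  fundus_image(round(px * 255), "uint8")
}

#' Read a binary lesion mask from PNG or TIFF
#'
#' @param path Mask file (any nonzero value is treated as lesion).
#' @param lesion_class Optional class label.
#' @return A `lesion_mask`.
#' @export
read_mask <- function(path, lesion_class = NA_character_) {
  px <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  lesion_mask((px > 0) * 1L, lesion_class)
}
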