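# Core raster containers.  Pixels are stored as plain numeric arrays in
# [row, column(, channel)] order; coordinates follow the 0-based, half-open
# convention used by the tiling bookkeeping.

#' Fundus image container
#'
#' @param pixels `H x W x 3` numeric array of intensities.
#' @param value_range Either `"uint8"` (intensities in 0..255) or
#'   `"normalized"` (real-valued, mean/std units).
#' @param roi_mask Optional `H x W` binary matrix marking the camera field of
#'   view.
#' @return A `fundus_image` object.
#' @export
fundus_image <- function(pixels, value_range = c("uint8", "normalized"),
                         roi_mask = NULL) {
  value_range <- match.arg(value_range)
  d <- dim(pixels)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L) stop("image dimensions must be >= 1")
  if (!is.null(roi_mask)) {
    if (!identical(dim(roi_mask), d[1:2]))
      stop("roi_mask dimensions must match the image")
    if (any(roi_mask != 0 & roi_mask != 1)) stop("roi_mask must be binary")
  }
  structure(list(pixels = pixels, value_range = value_range,
                 roi_mask = roi_mask),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("fundus_image %dx%d (%s)%s\n", d[1], d[2], x$value_range,
              if (is.null(x$roi_mask)) "" else ", with ROI mask"))
  invisible(x)
}

#' Binary lesion mask container
#'
#' @param pixels `H x W` matrix with values in \{0, 1\}.
#' @param lesion_class One of `"MA"`, `"EX"`, `"SE"`, `"HE"`, or `NA`.
#' @return A `lesion_mask` object.
#' @export
lesion_mask <- function(pixels, lesion_class = NA_character_) {
  if (is.null(dim(pixels)) || length(dim(pixels)) != 2L)
    stop("mask must be an H x W matrix")
  if (any(pixels != 0 & pixels != 1)) stop("mask must be binary")
  structure(list(pixels = pixels, lesion_class = lesion_class),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("lesion_mask %dx%d (%s), %d positive pixels\n", d[1], d[2],
              x$lesion_class, sum(x$pixels == 1)))
  invisible(x)
}

#' Bounding box (0-based, half-open)
#'
#' Rows `[row_start, row_end)` and columns `[col_start, col_end)`.
#'
#' @param row_start,row_end,col_start,col_end Pixel indices.
#' @return A `bounding_box` object.
#' @export
bounding_box <- function(row_start, row_end, col_start, col_end) {
  if (!(row_start < row_end && col_start < col_end))
    stop("bounding box must be nonempty")
  if (row_start < 0 || col_start < 0) stop("bounding box indices must be >= 0")
  structure(list(row_start = as.integer(row_start), row_end = as.integer(row_end),
                 col_start = as.integer(col_start), col_end = as.integer(col_end)),
            class = "bounding_box")
}

#' Crop a raster with a bounding box
#'
#' @param x A `fundus_image`, `lesion_mask`, matrix or 3-d array.
#' @param box A [bounding_box()].
#' @return The cropped object of the same kind.
#' @export
crop_raster <- function(x, box) {
  stopifnot(inherits(box, "bounding_box"))
  rows <- (box$row_start + 1L):box$row_end
  cols <- (box$col_start + 1L):box$col_end
  if (inherits(x, "fundus_image")) {
    roi <- if (is.null(x$roi_mask)) NULL else x$roi_mask[rows, cols, drop = FALSE]
    fundus_image(x$pixels[rows, cols, , drop = FALSE], x$value_range, roi)
  } else if (inherits(x, "lesion_mask")) {
    lesion_mask(x$pixels[rows, cols, drop = FALSE], x$lesion_class)
  } else if (length(dim(x)) == 3L) {
    x[rows, cols, , drop = FALSE]
  } else {
    x[rows, cols, drop = FALSE]
  }
}

pixels_of <- function(x) {
  if (inherits(x, "fundus_image") || inherits(x, "lesion_mask")) x$pixels else x
}
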