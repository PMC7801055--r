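# Sliding-window decomposition and overlap-averaged reconstruction.
# Offsets are 0-based top-left corners; footprints are half-open
# [row, row + window) x [col, col + window).  Offsets enumerate every
# stride-multiple plus, when the last multiple falls short, a final offset
# flush with the edge, so the union of footprints covers the whole image.

axis_offsets <- function(n, window, stride) {
  off <- seq.int(0L, n - window, by = stride)
  if (off[length(off)] != n - window) off <- c(off, n - window)
  as.integer(off)
}

#' Sliding-window tile grid
#'
#' @param image_height,image_width Image size in pixels.
#' @param window Tile side length (default 256).
#' @param stride Step between tile origins (default 64).
#' @return A `tile_grid` with 0-based `offsets` (matrix with columns `row`,
#'   `col`) and per-tile `valid_flags`, all `TRUE` initially.
#' @export
tile_grid <- function(image_height, image_width, window = 256L, stride = 64L) {
  if (window > min(image_height, image_width))
    stop(sprintf("image %dx%d smaller than window %d: pad or skip",
                 image_height, image_width, window))
  if (stride < 1L || stride > window)
    stop("stride must satisfy 1 <= stride <= window")
  ro <- axis_offsets(image_height, window, stride)
  co <- axis_offsets(image_width, window, stride)
  offsets <- cbind(row = rep(ro, times = length(co)),
                   col = rep(co, each = length(ro)))
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 window = as.integer(window), stride = as.integer(stride),
                 offsets = offsets,
                 valid_flags = rep(TRUE, nrow(offsets))),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid %dx%d, window %d, stride %d: %d tiles (%d valid)\n",
              x$image_height, x$image_width, x$window, x$stride,
              nrow(x$offsets), sum(x$valid_flags)))
  invisible(x)
}

#' Dice an image into overlapping tiles
#'
#' @param image A `fundus_image`, matrix, or `H x W x C` array.
#' @param window,stride Tile geometry; see [tile_grid()].
#' @return List with `grid` (a `tile_grid`) and `tiles` (list of arrays, one
#'   per grid offset).
#' @export
dice_image <- function(image, window = 256L, stride = 64L) {
  px <- pixels_of(image)
  d <- dim(px)
  grid <- tile_grid(d[1], d[2], window, stride)
  tiles <- lapply(seq_len(nrow(grid$offsets)), function(i) {
    r <- grid$offsets[i, "row"]; c <- grid$offsets[i, "col"]
    if (length(d) == 3L) px[r + seq_len(window), c + seq_len(window), , drop = FALSE]
    else px[r + seq_len(window), c + seq_len(window), drop = FALSE]
  })
  list(grid = grid, tiles = tiles)
}

#' Eliminate background tiles
#'
#' Clears the validity flag of every tile whose ROI coverage (fraction of
#' field-of-view pixels in its footprint) is below `min_roi_fraction`;
#' other flags are left untouched.
#'
#' @param grid A [tile_grid()].
#' @param roi_mask Binary `H x W` matrix matching the grid's image size.
#' @param min_roi_fraction Minimum ROI fraction for a tile to stay valid.
#' @return The updated `tile_grid`.
#' @export
filter_background <- function(grid, roi_mask, min_roi_fraction = 0.5) {
  stopifnot(inherits(grid, "tile_grid"))
  if (!identical(dim(roi_mask), c(grid$image_height, grid$image_width)))
    stop("roi_mask shape does not match the grid")
  w <- grid$window
  # integral image for O(1) per-tile ROI sums
  cs <- apply(apply(roi_mask, 2, cumsum), 1, cumsum)  # transposed cumulative
  sat <- matrix(0, grid$image_height + 1L, grid$image_width + 1L)
  sat[-1, -1] <- t(cs)
  for (i in seq_len(nrow(grid$offsets))) {
    if (!grid$valid_flags[i]) next
    r <- grid$offsets[i, "row"]; c <- grid$offsets[i, "col"]
    s <- sat[r + w + 1L, c + w + 1L] - sat[r + 1L, c + w + 1L] -
      sat[r + w + 1L, c + 1L] + sat[r + 1L, c + 1L]
    if (s / (w * w) < min_roi_fraction) grid$valid_flags[i] <- FALSE
  }
  grid
}

#' Number of valid tiles covering a pixel
#'
#' For an interior pixel of a large image at the default window 256 /
#' stride 64 geometry this is 16 (4 windows per axis).
#'
#' @param grid A [tile_grid()].
#' @param pixel Length-2 vector `(row, col)`, 0-based.
#' @return Integer count.
#' @export
coverage_count <- function(grid, pixel) {
  stopifnot(inherits(grid, "tile_grid"), length(pixel) == 2L)
  r <- pixel[1]; c <- pixel[2]
  if (r < 0 || c < 0 || r >= grid$image_height || c >= grid$image_width)
    stop("pixel out of bounds")
  w <- grid$window
  sum(grid$valid_flags &
        grid$offsets[, "row"] <= r & r < grid$offsets[, "row"] + w &
        grid$offsets[, "col"] <= c & c < grid$offsets[, "col"] + w)
}

#' Merge per-tile predictions by overlap averaging
#'
#' Every output pixel is the arithmetic mean of the predictions of all valid
#' tiles whose footprint contains it. Pixels covered by no valid tile are
#' returned as `NA` rather than silently zeroed.
#'
#' @param tile_predictions List of `window x window` numeric rasters, one
#'   per *valid* tile in grid order (or one per tile, invalid entries
#'   ignored).
#' @param grid A [tile_grid()].
#' @return `H x W` numeric matrix of averaged predictions.
#' @export
merge_tiles <- function(tile_predictions, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  w <- grid$window
  valid_idx <- which(grid$valid_flags)
  if (length(tile_predictions) == nrow(grid$offsets)) {
    preds <- tile_predictions[valid_idx]
  } else if (length(tile_predictions) == length(valid_idx)) {
    preds <- tile_predictions
  } else {
    stop("need one prediction per (valid) tile")
  }
  acc <- matrix(0, grid$image_height, grid$image_width)
  cnt <- matrix(0L, grid$image_height, grid$image_width)
  for (k in seq_along(valid_idx)) {
    p <- preds[[k]]
    if (length(dim(p)) == 3L && dim(p)[3] == 1L) p <- p[, , 1]
    if (length(dim(p)) == 4L) p <- array(p, dim(p)[1:2])
    if (!identical(dim(p), c(w, w)))
      stop(sprintf("prediction %d has shape %s, expected %dx%d",
                   k, paste(dim(p), collapse = "x"), w, w))
    i <- valid_idx[k]
    rows <- grid$offsets[i, "row"] + seq_len(w)
    cols <- grid$offsets[i, "col"] + seq_len(w)
    acc[rows, cols] <- acc[rows, cols] + p
    cnt[rows, cols] <- cnt[rows, cols] + 1L
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  out
}

#' Serialize a tile grid to JSON
#'
#' @param grid A [tile_grid()].
#' @param path Output file; when `NULL` the JSON string is returned.
#' @export
tile_grid_to_json <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "tile_grid"))
  obj <- list(image_height = grid$image_height, image_width = grid$image_width,
              window = grid$window, stride = grid$stride,
              offsets = unname(apply(grid$offsets, 1, as.list)),
              valid_flags = grid$valid_flags)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a tile grid from JSON
#'
#' @param path File written by [tile_grid_to_json()].
#' @return A `tile_grid`.
#' @export
tile_grid_from_json <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  g <- tile_grid(o$image_height, o$image_width, o$window, o$stride)
  g$valid_flags <- as.logical(o$valid_flags)
  g
}
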