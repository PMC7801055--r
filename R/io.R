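# Output formats: merged probability maps as 32-bit float TIFF, binary
# masks as PNG, normalization statistics as JSON sidecars.

#' Write a probability map as 32-bit float TIFF
#'
#' `NA` pixels (covered by no valid tile) are written as -1.
#'
#' @param prob Numeric matrix in `[0, 1]` (or `NA`).
#' @param path Output file.
#' @export
write_probability_tiff <- function(prob, path) {
  p <- prob
  attributes(p) <- list(dim = dim(p))
  p[is.na(p)] <- -1
  # float TIFF stores the -1 sentinel fine; writeTIFF warns about any
  # value outside [0, 1]
  suppressWarnings(tiff::writeTIFF(p, path, bits.per.sample = 32L,
                                   reduce = TRUE))
  invisible(path)
}

#' Write normalization statistics as JSON
#'
#' @param stats A `norm_stats`.
#' @param path Output file.
#' @export
norm_stats_to_json <- function(stats, path = NULL) {
  stopifnot(inherits(stats, "norm_stats"))
  js <- jsonlite::toJSON(list(mean = stats$mean, std = stats$std), digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read normalization statistics from JSON
#'
#' @param path File written by [norm_stats_to_json()].
#' @return A `norm_stats`.
#' @export
norm_stats_from_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  structure(list(mean = as.numeric(o$mean), std = as.numeric(o$std)),
            class = "norm_stats")
}
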