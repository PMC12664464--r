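# Map summaries: anatomy masking, cumulative frequency (percentile)
# analysis and quartile summaries of resolution and g-factor maps.

#' Threshold-based anatomy mask
#'
#' Pixels at or above `rel_threshold` times the image maximum, followed
#' by one binary closing pass (3x3 box) to fill interior holes.
#'
#' @param image real non-negative matrix (a reconstruction).
#' @param rel_threshold fraction of the maximum (default 0.05).
#' @return logical matrix.
#' @export
anatomy_mask <- function(image, rel_threshold = 0.05) {
  stopifnot(rel_threshold > 0, rel_threshold < 1)
  m <- image >= rel_threshold * max(image)
  if (!any(m)) stop("anatomy mask is empty")
  closed <- EBImage::closing(EBImage::Image(m * 1),
                             EBImage::makeBrush(3, shape = "box"))
  matrix(as.numeric(closed) > 0.5, nrow(image), ncol(image))
}

#' Cumulative frequency analysis (percentile curve) of a map
#'
#' Empirical quantiles (linear interpolation between order statistics,
#' type 7) of the masked, valid (non-NA) pixels of a map.
#'
#' @param map real matrix (resolution widths or g values; NA = invalid).
#' @param mask logical matrix selecting pixels, or NULL for all.
#' @param percents percentages in `[0, 100]` (default 1..99).
#' @return a `percentile_curve`: data.frame with columns `percent` and
#'   `value`, non-decreasing in `percent`.
#' @export
cumulative_frequency <- function(map, mask = NULL, percents = 1:99) {
  stopifnot(all(percents >= 0 & percents <= 100))
  vals <- if (is.null(mask)) as.vector(map) else map[mask]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no valid pixels under the mask")
  out <- data.frame(percent = percents,
                    value = unname(stats::quantile(vals, percents / 100,
                                                   type = 7)))
  class(out) <- c("percentile_curve", "data.frame")
  out
}

#' Quartile summary of a map over a mask
#'
#' @inheritParams cumulative_frequency
#' @return data.frame with one row: `q25`, `q50`, `q75`, `frac_above_1`
#'   (fraction of valid pixels exceeding 1, the natural reference level
#'   for both width and g maps), `n_valid` and `n_invalid`.
#' @export
summarize_map <- function(map, mask = NULL) {
  vals <- if (is.null(mask)) as.vector(map) else map[mask]
  n_invalid <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no valid pixels under the mask")
  q <- unname(stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7))
  data.frame(q25 = q[1], q50 = q[2], q75 = q[3],
             frac_above_1 = mean(vals > 1),
             n_valid = length(vals), n_invalid = n_invalid)
}

#' Write a real-valued map as a CSV matrix
#' @param map real matrix.
#' @param path file path.
#' @export
write_map_csv <- function(map, path) {
  utils::write.table(map, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  unname(as.matrix(utils::read.table(path, sep = ",")))
}
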