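#' Per-probeset mean/SD dispersion table
#'
#' Computes, for every probeset, the mean and standard deviation (n - 1
#' denominator) of its log2 values across hybridizations, labelled with the
#' probeset's control class (or `background`). This is the probeset-level
#' precision screen: control classes added later in the protocol should show
#' systematically lower SDs than classes subject to more processing.
#'
#' @param matrix an [expression_matrix()] with N >= 2 hybridizations.
#' @param registry a [control_registry()].
#' @return a `dispersion_table` data.frame with columns probeset_id, mean,
#'   sd, control_class.
#' @export
mean_sd_table <- function(matrix, registry) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (nrow(matrix) < 2L)
    stop("SD is undefined with fewer than 2 hybridizations")
  x <- unclass(matrix)
  cls <- registry$class[match(colnames(x), registry$probeset_id)]
  cls[is.na(cls)] <- "background"
  out <- data.frame(probeset_id = colnames(x),
                    mean = colMeans(x),
                    sd = apply(x, 2L, stats::sd),
                    control_class = cls,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("dispersion_table", "data.frame"))
}

#' Moving-average background curve
#'
#' Sorts the background probesets by mean intensity and smooths with a
#' centered moving average of `window` points (the window shrinks
#' symmetrically at the edges). Both the smoothed mean and the smoothed SD
#' along the mean-sorted axis are returned, giving the background reference
#' line against which control-probeset dispersion is judged.
#'
#' @param table a `dispersion_table` from [mean_sd_table()].
#' @param window number of points in the moving average (default 100).
#' @return data.frame with columns mean, smoothed_mean, smoothed_sd,
#'   ordered by mean.
#' @export
background_curve <- function(table, window = 100L) {
  if (window < 1L) stop("window must be at least 1")
  bg <- table[table$control_class == "background", , drop = FALSE]
  if (!nrow(bg)) stop("no background probesets in dispersion table")
  bg <- bg[order(bg$mean), , drop = FALSE]
  n <- nrow(bg)
  half <- (as.integer(window) - 1L) %/% 2L
  sm <- function(v) {
    vapply(seq_len(n), function(i) {
      h <- min(half, i - 1L, n - i)   # symmetric edge shrinkage
      mean(v[(i - h):(i + h)])
    }, numeric(1L))
  }
  data.frame(mean = bg$mean,
             smoothed_mean = sm(bg$mean),
             smoothed_sd = sm(bg$sd),
             row.names = NULL)
}

#' Median SD per control class
#'
#' Convenience summary used to check the expected precision ordering
#' (hybridization <= polyA <= endogenous/degradation).
#'
#' @param table a `dispersion_table`.
#' @return named numeric vector of class-median SDs.
#' @export
class_median_sd <- function(table) {
  vapply(split(table$sd, table$control_class), stats::median, numeric(1L))
}
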