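#' Quantile normalization to the global median
#'
#' Forces every hybridization onto a common reference distribution: at each
#' rank the reference value is the median across hybridizations of the
#' rank-th order statistic. Ties within a hybridization receive the mean of
#' the reference values over the ranks they occupy, so the operation is
#' deterministic and preserves within-array rank order.
#'
#' @param matrix an [expression_matrix()], N >= 2 hybridizations.
#' @return a new [expression_matrix()] in which every hybridization shares
#'   one sorted multiset of values.
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  x <- unclass(matrix)
  n <- nrow(x)
  if (n < 2L) stop("quantile normalization needs at least 2 hybridizations")
  sorted <- apply(x, 1L, sort)             # K x N, each column one array
  reference <- apply(sorted, 1L, stats::median)
  out <- x
  for (i in seq_len(n)) {
    r <- rank(x[i, ], ties.method = "min")
    # mean of reference values over the block of ranks each tie group occupies
    cnt <- table(r)
    starts <- as.integer(names(cnt))
    val <- vapply(seq_along(starts), function(j) {
      mean(reference[starts[j]:(starts[j] + cnt[[j]] - 1L)])
    }, numeric(1L))
    out[i, ] <- val[match(r, starts)]
  }
  expression_matrix(out, log2_scale = attr(matrix, "log2_scale"))
}

#' 75th-percentile "brightness-scaled" normalization
#'
#' For each hybridization, computes the 75th percentile of its non-control
#' (background) probeset log2 intensities and subtracts that scalar from the
#' target probesets (by default the control probesets of interest).
#' Background probesets pass through unchanged unless
#' `apply_to_background = TRUE`. A per-array affine shift: within-array
#' contrasts between targets are preserved exactly.
#'
#' @param matrix an [expression_matrix()].
#' @param background_ids probeset IDs forming the background set (non-empty,
#'   disjoint from targets).
#' @param target_ids probeset IDs to shift; defaults to all non-background
#'   probesets.
#' @param probs percentile as a fraction (default 0.75).
#' @param type percentile convention passed to [stats::quantile()]
#'   (default 7: linear interpolation between order statistics).
#' @param apply_to_background also shift the background probesets.
#' @return a new [expression_matrix()]; the input is not modified.
#' @export
percentile75_normalize <- function(matrix, background_ids,
                                   target_ids = NULL, probs = 0.75,
                                   type = 7L, apply_to_background = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  x <- unclass(matrix)
  background_ids <- intersect(background_ids, colnames(x))
  if (!length(background_ids)) stop("background probeset set is empty")
  if (is.null(target_ids))
    target_ids <- setdiff(colnames(x), background_ids)
  if (length(intersect(target_ids, background_ids)))
    stop("target and background probeset sets must be disjoint")
  q75 <- apply(x[, background_ids, drop = FALSE], 1L, stats::quantile,
               probs = probs, type = type, names = FALSE)
  shift_ids <- if (apply_to_background) c(target_ids, background_ids) else target_ids
  out <- x
  out[, shift_ids] <- out[, shift_ids, drop = FALSE] - q75
  expression_matrix(out, log2_scale = attr(matrix, "log2_scale"))
}

#' Normalize an expression matrix
#'
#' Dispatcher over the two supported schemes plus pass-through.
#'
#' @param matrix an [expression_matrix()].
#' @param method `"quantile"`, `"p75"` or `"none"`.
#' @param registry required for `"p75"`: probesets absent from the registry
#'   form the background set.
#' @param ... further arguments to the underlying scheme.
#' @return a normalized [expression_matrix()].
#' @export
normalize_matrix <- function(matrix, method = c("p75", "quantile", "none"),
                             registry = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         none = matrix,
         quantile = quantile_normalize(matrix),
         p75 = {
           if (is.null(registry))
             stop("p75 normalization needs a registry to define background probesets")
           bg <- setdiff(colnames(matrix), registry$probeset_id)
           percentile75_normalize(matrix, background_ids = bg, ...)
         })
}
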