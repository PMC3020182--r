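#' Per-transcript summary signals from a control block
#'
#' Summarizes each transcript as the unweighted mean of its probesets' log2
#' values, or as the 3' probeset(s) only.
#'
#' @param block an [expression_matrix()] restricted to one control class.
#' @param registry a [control_registry()].
#' @param method `"mean"` (all positions/revisions) or `"three_prime"`.
#' @return numeric matrix, hybridizations x transcripts.
#' @export
transcript_signals <- function(block, registry, method = c("mean", "three_prime")) {
  method <- match.arg(method)
  reg <- registry[match(colnames(block), registry$probeset_id), , drop = FALSE]
  if (anyNA(reg$transcript)) stop("block contains probesets absent from the registry")
  keep <- if (method == "three_prime") reg$position == "3'" else rep(TRUE, nrow(reg))
  tx <- unique(reg$transcript)
  x <- unclass(block)
  out <- vapply(tx, function(t) {
    cols <- which(reg$transcript == t & keep)
    if (!length(cols)) return(rep(NA_real_, nrow(x)))
    rowMeans(x[, cols, drop = FALSE])
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x), dimnames = list(rownames(x), tx))
  out[, colSums(is.na(out)) == 0L, drop = FALSE]
}

#' Spike-in concentration-response correlation
#'
#' Squared Pearson correlation between log2 spike concentration and the
#' per-transcript log2 signal of one hybridization. Values above ~0.95 are
#' expected for technically sound samples; a collapse of the spike-in
#' response (e.g. a labeling failure) destroys the correlation.
#'
#' @param signal named numeric vector of per-transcript log2 signals (>= 3
#'   transcripts).
#' @param design a [spikein_design()].
#' @return R^2 as a numeric scalar carrying attribute `degenerate` (TRUE
#'   when the signal has zero variance, in which case R^2 is reported as 0).
#' @export
polya_correlation <- function(signal, design) {
  tx <- intersect(names(design$concentrations), names(signal))
  if (length(tx) < 3L) stop("need at least 3 transcripts with defined signal")
  s <- signal[tx]
  lc <- log2(design$concentrations[tx])
  if (stats::sd(s) < .Machine$double.eps^0.5)
    return(structure(0, degenerate = TRUE))
  structure(unname(stats::cor(lc, s)^2), degenerate = FALSE)
}

#' 3'/5' signal ratio
#'
#' Linear-scale ratio of the 3' to 5' signal, `2^(log2_3p - log2_5p)`.
#' Ratios above the tolerance (conventionally 3) indicate transcript
#' degradation or poor labeling processivity: reverse transcription starts
#' at the 3' poly(A) end, so a damaged or poorly processed template loses
#' 5' signal first.
#'
#' @param log2_3p,log2_5p finite log2 intensities (vectorized).
#' @return linear-scale ratio(s).
#' @export
three_prime_five_prime_ratio <- function(log2_3p, log2_5p) {
  stopifnot(all(is.finite(log2_3p)), all(is.finite(log2_5p)))
  2^(log2_3p - log2_5p)
}

#' Per-transcript 3'/5' ratios across hybridizations
#'
#' For every transcript that carries both 5' and 3' probesets in the given
#' classes, computes [three_prime_five_prime_ratio()] from the mean 3' and
#' mean 5' log2 signals of each hybridization.
#'
#' @param matrix an [expression_matrix()].
#' @param registry a [control_registry()].
#' @param classes control classes to scan (default polyA and
#'   rna_degradation).
#' @return long data.frame: hybridization_id, class, transcript, ratio.
#' @export
transcript_3p5p_ratios <- function(matrix, registry,
                                   classes = c("polyA", "rna_degradation")) {
  reg <- registry[registry$class %in% classes, , drop = FALSE]
  reg <- reg[reg$probeset_id %in% colnames(matrix), , drop = FALSE]
  x <- unclass(matrix)
  out <- list()
  for (key in unique(paste(reg$class, reg$transcript, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    rows <- reg$class == parts[1L] & reg$transcript == parts[2L]
    p5 <- reg$probeset_id[rows & reg$position == "5'"]
    p3 <- reg$probeset_id[rows & reg$position == "3'"]
    if (!length(p5) || !length(p3)) next
    m5 <- rowMeans(x[, p5, drop = FALSE])
    m3 <- rowMeans(x[, p3, drop = FALSE])
    out[[key]] <- data.frame(hybridization_id = rownames(x),
                             class = parts[1L], transcript = parts[2L],
                             ratio = three_prime_five_prime_ratio(m3, m5),
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Check the expected spike-in signal ordering
#'
#' Walks the expected ranking (highest signal first) and reports every
#' adjacent pair that violates the strict inequality, ties included.
#'
#' @param signal named numeric vector of per-transcript signals.
#' @param expected_order character vector ranking transcripts, highest
#'   expected signal first.
#' @return data.frame of violations: higher, lower, higher_value,
#'   lower_value (zero rows when the ordering holds).
#' @export
ordering_check <- function(signal, expected_order) {
  missing <- setdiff(expected_order, names(signal))
  if (length(missing))
    stop("signal missing for transcript(s): ", paste(missing, collapse = ", "))
  s <- signal[expected_order]
  bad <- which(diff(s) >= 0)  # s[i] <= s[i+1] violates s[i] > s[i+1]
  data.frame(higher = expected_order[bad],
             lower = expected_order[bad + 1L],
             higher_value = unname(s[bad]),
             lower_value = unname(s[bad + 1L]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Difference profile between experiment means and one hybridization
#'
#' Per-transcript difference `experiment mean - sample value`; for an array
#' whose spike-in response collapsed to background, this difference is
#' itself linear in log2 concentration.
#'
#' @param experiment_means,sample_values named numeric vectors over the
#'   same transcript set.
#' @return named numeric vector of differences.
#' @export
difference_profile <- function(experiment_means, sample_values) {
  if (!setequal(names(experiment_means), names(sample_values)) ||
      length(experiment_means) != length(sample_values))
    stop("experiment and sample transcript sets differ")
  experiment_means - sample_values[names(experiment_means)]
}

#' Scalar QC metrics for every hybridization
#'
#' Computes the spike-in concentration-response R^2, the per-transcript
#' 3'/5' ratios and the expected-ordering violations for each
#' hybridization.
#'
#' @param matrix an [expression_matrix()].
#' @param registry a [control_registry()].
#' @param design a [spikein_design()].
#' @param config a [qc_config()].
#' @return list with `polya_r2` (named numeric), `degenerate` (named
#'   logical), `ratios` (long data.frame), `ordering` (long data.frame of
#'   violations with hybridization_id).
#' @export
compute_qc_metrics <- function(matrix, registry, design, config = qc_config()) {
  blocks <- partition_by_class(matrix, registry, require_classes = "polyA")
  sig <- transcript_signals(blocks$polyA, registry)
  r2 <- numeric(nrow(sig)); degen <- logical(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    v <- polya_correlation(sig[i, ], design)
    r2[i] <- v; degen[i] <- attr(v, "degenerate")
  }
  names(r2) <- names(degen) <- rownames(sig)
  ord <- lapply(rownames(sig), function(h) {
    v <- ordering_check(sig[h, ], design$expected_order)
    if (nrow(v)) cbind(hybridization_id = h, v) else NULL
  })
  ord <- do.call(rbind, c(ord, list(make.row.names = FALSE)))
  if (is.null(ord))
    ord <- data.frame(hybridization_id = character(0), higher = character(0),
                      lower = character(0), higher_value = numeric(0),
                      lower_value = numeric(0))
  list(polya_r2 = r2, degenerate = degen,
       ratios = transcript_3p5p_ratios(matrix, registry),
       ordering = ord)
}

#' F-distribution control limit for Hotelling T-squared
#'
#' `T2_lim = A (N - 1) / (N - A) * F_{1-alpha}(A, N - A)` on calibration
#' data.
#'
#' @param model a `pca_model`.
#' @param A component count (defaults to the selected A).
#' @param alpha significance level (default 0.05).
#' @return numeric limit.
#' @export
t2_limit <- function(model, A = model$A, alpha = 0.05) {
  n <- model$N
  if (A >= n) stop("A must be smaller than N")
  A * (n - 1) / (n - A) * stats::qf(1 - alpha, A, n - A)
}

#' Jackson-Mudholkar control limit for Q residuals
#'
#' Approximate upper control limit for the squared prediction error from
#' the residual eigenvalue moments theta_r = sum_{j>A} lambda_j^r.
#'
#' @param model a `pca_model` (its full eigenvalue spectrum is used).
#' @param A component count (defaults to the selected A).
#' @param alpha significance level (default 0.05).
#' @return numeric limit (0 when no residual variance remains).
#' @export
q_limit <- function(model, A = model$A, alpha = 0.05) {
  lam <- model$eigenvalues_all
  lam <- lam[-seq_len(min(A, length(lam)))]
  th1 <- sum(lam); th2 <- sum(lam^2); th3 <- sum(lam^3)
  if (th1 <= 0 || th2 <= 0) return(0)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 == 0) h0 <- 1e-4
  ca <- stats::qnorm(1 - alpha)
  th1 * (ca * sqrt(2 * th2 * h0^2) / th1 + 1 +
           th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' Aggregate diagnostics and metrics into a QC report
#'
#' Combines the per-class PCA diagnostics with the scalar spike-in and
#' degradation metrics into one row per hybridization, and attributes each
#' flagged hybridization to a protocol stage. A sample is flagged in a
#' class model when its Q or T2 ranks within the top `rank_depth` AND
#' exceeds the corresponding 95% control limit. Stage attribution follows
#' the control-addition order: an anomaly visible in the hybridization
#' class (added last) implicates hybridization/scanning and explains
#' downstream classes too; otherwise a polyA-class or spike-in metric
#' anomaly implicates amplification/labeling; otherwise degradation or
#' endogenous anomalies implicate sample RNA quality.
#'
#' @param fits output of [layered_fit()].
#' @param metrics output of [compute_qc_metrics()].
#' @param config a [qc_config()].
#' @return a `qc_report` list with `table` (one row per hybridization:
#'   metric values, per-class flags, attributed stage) and `flags` (long
#'   data.frame: hybridization_id, flag, value, threshold).
#' @export
aggregate_qc <- function(fits, metrics, config = qc_config()) {
  ids <- fits[[1L]]$diagnostics$hybridization_id
  for (cl in names(fits))
    if (!setequal(fits[[cl]]$diagnostics$hybridization_id, ids))
      stop("class '", cl, "' diagnostics cover a different hybridization set")
  if (!all(ids %in% names(metrics$polya_r2)))
    stop("metric results missing for hybridization(s): ",
         paste(setdiff(ids, names(metrics$polya_r2)), collapse = ", "))

  r <- config$rank_depth
  flags <- list()
  add_flag <- function(id, flag, value, threshold) {
    flags[[length(flags) + 1L]] <<- data.frame(
      hybridization_id = id, flag = flag, value = value,
      threshold = threshold, stringsAsFactors = FALSE)
  }

  tab <- data.frame(hybridization_id = ids, stringsAsFactors = FALSE)
  tab$polya_r2 <- unname(metrics$polya_r2[ids])
  tab$low_polya_r2 <- tab$polya_r2 < config$r2_threshold |
    metrics$degenerate[ids]
  for (i in which(tab$low_polya_r2))
    add_flag(ids[i], "low_polya_r2", tab$polya_r2[i], config$r2_threshold)

  tab$ordering_violation <- ids %in% metrics$ordering$hybridization_id
  for (i in which(tab$ordering_violation)) {
    v <- metrics$ordering[metrics$ordering$hybridization_id == ids[i], ][1L, ]
    add_flag(ids[i], paste0("ordering_violation:", v$higher, ">", v$lower),
             v$lower_value - v$higher_value, 0)
  }

  elevated <- metrics$ratios[metrics$ratios$ratio > config$three_five_tolerance, ,
                             drop = FALSE]
  tab$elevated_3p5p <- ids %in% elevated$hybridization_id
  tab$elevated_3p5p_rnad <- ids %in%
    elevated$hybridization_id[elevated$class == "rna_degradation"]
  for (i in seq_len(nrow(elevated)))
    add_flag(elevated$hybridization_id[i],
             paste0("elevated_3p5p:", elevated$transcript[i]),
             elevated$ratio[i], config$three_five_tolerance)

  for (cl in names(fits)) {
    d <- fits[[cl]]$diagnostics
    d <- d[match(ids, d$hybridization_id), ]
    m <- fits[[cl]]$model
    qlim <- q_limit(m); tlim <- t2_limit(m)
    hq <- d$q_rank <= r & d$Q > qlim
    ht <- d$t2_rank <= r & d$T2 > tlim
    tab[[paste0("high_Q_", cl)]] <- hq
    tab[[paste0("high_T2_", cl)]] <- ht
    for (i in which(hq)) add_flag(ids[i], paste0("high_Q:", cl), d$Q[i], qlim)
    for (i in which(ht)) add_flag(ids[i], paste0("high_T2:", cl), d$T2[i], tlim)
  }

  hyb_anom <- tab$high_Q_hybridization | tab$high_T2_hybridization
  polya_anom <- tab$high_Q_polyA | tab$high_T2_polyA | tab$low_polya_r2 |
    tab$ordering_violation | (tab$elevated_3p5p & !tab$elevated_3p5p_rnad)
  sample_anom <- tab$high_Q_rna_degradation | tab$high_T2_rna_degradation |
    tab$high_Q_endogenous | tab$high_T2_endogenous | tab$elevated_3p5p_rnad
  tab$n_class_anomalies <- (tab$high_Q_hybridization | tab$high_T2_hybridization) +
    (tab$high_Q_polyA | tab$high_T2_polyA) +
    (tab$high_Q_rna_degradation | tab$high_T2_rna_degradation) +
    (tab$high_Q_endogenous | tab$high_T2_endogenous)
  tab$stage <- ifelse(hyb_anom, "hybridization/scanning",
                ifelse(polya_anom, "amplification/labeling",
                  ifelse(sample_anom, "sample RNA quality", "none")))
  tab$multi_class <- tab$n_class_anomalies >= 4L

  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(hybridization_id = character(0), flag = character(0),
               value = numeric(0), threshold = numeric(0))
  structure(list(table = tab, flags = flags, config = config),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  n_flagged <- sum(x$table$stage != "none")
  cat(sprintf("qc_report: %d hybridizations, %d flagged\n",
              nrow(x$table), n_flagged))
  if (n_flagged) {
    sub <- x$table[x$table$stage != "none",
                   c("hybridization_id", "polya_r2", "stage")]
    print(sub, row.names = FALSE)
  }
  invisible(x)
}
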