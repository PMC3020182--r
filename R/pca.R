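#' Mean-center a data block
#'
#' Centers each column (probeset) of an N x K block to mean zero. Variables
#' are not variance scaled: control blocks are already on a common log2
#' scale and scaling would inflate the influence of quiet probesets.
#'
#' @param X numeric N x K matrix, N >= 2.
#' @return list with `centered` (N x K) and `mean` (length-K vector).
#' @export
mean_center <- function(X) {
  X <- as.matrix(unclass(X))
  if (nrow(X) < 2L) stop("mean centering needs at least 2 samples")
  mu <- colMeans(X)
  list(centered = sweep(X, 2L, mu, "-"), mean = mu)
}

#' Fit a principal component model to a centered block
#'
#' Singular value decomposition of the centered block `Xc = T P'` with
#' orthonormal loadings P. Eigenvalues are the score variances
#' `lambda_a = d_a^2 / (N - 1)` and percent variance is taken against the
#' full-rank total. Each loading column is oriented so that its
#' largest-magnitude element is positive, making score plots reproducible.
#'
#' @param Xc centered N x K matrix (column means zero).
#' @param A_max number of components to retain; must not exceed
#'   min(N - 1, K) (truncated with a warning if it exceeds the numerical
#'   rank).
#' @param center mean vector recorded in the model (defaults to zeros; pass
#'   the vector from [mean_center()] so new samples can be centered).
#' @return a `pca_model`: list with mean, loadings (K x A_max), scores
#'   (N x A_max), eigenvalues, pct_variance, cum_pct_variance,
#'   total_variance, rank, N, K. `A` (the selected component count) is NA
#'   until chosen by [select_components()].
#' @export
fit_pca <- function(Xc, A_max = NULL, center = NULL) {
  Xc <- as.matrix(unclass(Xc))
  n <- nrow(Xc); k <- ncol(Xc)
  full <- min(n - 1L, k)
  if (is.null(A_max)) A_max <- full
  if (A_max > full)
    stop("A_max must not exceed min(N - 1, K) = ", full)
  sv <- svd(Xc)
  d <- sv$d
  rank <- sum(d > max(d[1L], 1) * 1e-12)
  if (A_max > rank) {
    warning("A_max = ", A_max, " exceeds numerical rank ", rank,
            "; truncating")
    A_max <- rank
  }
  P <- sv$v[, seq_len(A_max), drop = FALSE]
  # sign convention: largest-|.| loading element positive per component
  flip <- vapply(seq_len(A_max), function(a) {
    sign(P[which.max(abs(P[, a])), a])
  }, numeric(1L))
  P <- sweep(P, 2L, flip, "*")
  Tsc <- Xc %*% P
  lambda_full <- d^2 / (n - 1L)
  lambda <- lambda_full[seq_len(A_max)]
  total <- sum(lambda_full)
  pct <- 100 * lambda / total
  rownames(P) <- colnames(Xc)
  rownames(Tsc) <- rownames(Xc)
  colnames(P) <- colnames(Tsc) <- paste0("PC", seq_len(A_max))
  structure(list(mean = if (is.null(center)) numeric(k) else center,
                 loadings = P, scores = Tsc,
                 eigenvalues = lambda,
                 eigenvalues_all = lambda_full[seq_len(full)],
                 pct_variance = pct,
                 cum_pct_variance = cumsum(pct),
                 total_variance = total,
                 rank = rank, N = n, K = k,
                 rmsec = NULL, rmsecv = NULL, A = NA_integer_),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: N=%d, K=%d, %d component(s) retained", x$N, x$K,
              ncol(x$loadings)))
  if (!is.na(x$A))
    cat(sprintf("; A=%d (%.1f%% cumulative variance)", x$A,
                x$cum_pct_variance[x$A]))
  cat("\n")
  invisible(x)
}

#' Venetian-blinds cross-validation segments
#'
#' Sample i (0-based, in the given order) joins segment `i mod k`, so
#' consecutive samples are spread across all k segments.
#'
#' @param n number of samples.
#' @param k number of splits, 2 <= k <= n.
#' @return integer vector of segment labels 1..k (segment j holds the
#'   0-based indices congruent to j - 1 mod k).
#' @export
venetian_blinds <- function(n, k) {
  if (k < 2L || k > n) stop("splits must satisfy 2 <= k <= n")
  ((seq_len(n) - 1L) %% as.integer(k)) + 1L
}

#' Random-subset cross-validation segments
#'
#' A random permutation of balanced segment labels; used as a consistency
#' check on the venetian-blinds component choice.
#'
#' @param n number of samples.
#' @param k number of splits.
#' @return integer vector of segment labels 1..k.
#' @export
random_subset_assignment <- function(n, k) {
  if (k < 2L || k > n) stop("splits must satisfy 2 <= k <= n")
  sample(((seq_len(n) - 1L) %% as.integer(k)) + 1L)
}

#' Trap replicate hybridizations into one CV segment
#'
#' Re-hybridizations of a single aliquot must not be split between training
#' and test sets, or the cross-validation error is optimistically biased.
#' All members of a replicate group are moved to the segment of the group's
#' first member; singleton groups are untouched.
#'
#' @param assignment integer segment labels (from [venetian_blinds()] or
#'   [random_subset_assignment()]), one per sample in metadata order.
#' @param metadata a [hybridization_metadata()] whose rows parallel
#'   `assignment`.
#' @return adjusted integer assignment.
#' @export
trap_replicates <- function(assignment, metadata) {
  groups <- metadata$replicate_group
  if (length(groups) != length(assignment))
    stop("metadata and assignment lengths differ")
  if (any(is.na(groups))) stop("replicate_group must be defined for all samples")
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) assignment[idx] <- assignment[idx[1L]]
  }
  assignment
}

#' Cross-validated and calibration reconstruction error curves
#'
#' For each held-out segment, the model is refit on the remaining rows
#' (re-centered by the training mean) and the held-out rows are
#' reconstructed from the first `a` training loadings;
#' `RMSECV(a) = sqrt(sum(residual^2) / (N * K))`. RMSEC(a) is computed
#' analogously from the full-data fit's own residuals.
#'
#' Two reconstruction schemes are available for the held-out rows. The
#' default, `"elementwise"`, predicts each variable of a held-out sample
#' from the sample's other variables through the training loadings
#' (missing-data regression), so over-fitted components degrade prediction
#' and the RMSECV curve attains a genuine minimum. The `"rowwise"` scheme
#' projects the full held-out row onto the loadings; its residual can only
#' shrink as components are added, so the curve is typically monotone and
#' component choice then rests entirely on the parsimony tolerance of
#' [select_components()].
#'
#' @param Xc centered N x K block.
#' @param A_max maximum component count to evaluate; every training fold
#'   must keep at least `A_max + 1` rows.
#' @param assignment integer CV segment labels, one per row.
#' @param scheme `"elementwise"` (default) or `"rowwise"`.
#' @return list with numeric vectors `rmsec` and `rmsecv`, each of length
#'   `A_max` (index a = component count).
#' @export
cross_validate_pca <- function(Xc, A_max, assignment,
                               scheme = c("elementwise", "rowwise")) {
  scheme <- match.arg(scheme)
  Xc <- as.matrix(unclass(Xc))
  n <- nrow(Xc); k <- ncol(Xc)
  if (length(assignment) != n) stop("assignment length must equal N")
  segs <- sort(unique(assignment))
  press <- numeric(A_max)
  for (s in segs) {
    test <- which(assignment == s)
    train <- which(assignment != s)
    if (length(train) < A_max + 1L)
      stop(sprintf("training fold for segment %s has %d rows; need at least A_max + 1 = %d",
                   s, length(train), A_max + 1L))
    ctr <- mean_center(Xc[train, , drop = FALSE])
    P <- svd(ctr$centered, nu = 0L, nv = min(A_max, min(length(train) - 1L, k)))$v
    Xt <- sweep(Xc[test, , drop = FALSE], 2L, ctr$mean, "-")
    if (scheme == "rowwise") {
      Tt <- Xt %*% P
      resid <- Xt
      for (a in seq_len(A_max)) {
        if (a <= ncol(P))
          resid <- Xt - Tt[, seq_len(a), drop = FALSE] %*% t(P[, seq_len(a), drop = FALSE])
        press[a] <- press[a] + sum(resid^2)
      }
    } else {
      # With orthonormal loadings, predicting variable j of a held-out row
      # from its other variables (least-squares scores on P without row j)
      # has the closed form e_j = (x_j - [x P_a P_a']_j) / (1 - h_j) with
      # variable leverage h_j = ||P_a[j,]||^2 (Sherman-Morrison downdate).
      for (a in seq_len(A_max)) {
        aa <- min(a, ncol(P))
        Pa <- P[, seq_len(aa), drop = FALSE]
        E <- Xt - (Xt %*% Pa) %*% t(Pa)
        h <- rowSums(Pa^2)
        denom <- pmax(1 - h, 1e-8)
        press[a] <- press[a] + sum(sweep(E, 2L, denom, "/")^2)
      }
    }
  }
  full <- fit_pca(Xc, A_max = min(A_max, min(n - 1L, k)))
  ss_cal <- numeric(A_max)
  Tf <- full$scores; Pf <- full$loadings
  for (a in seq_len(A_max)) {
    aa <- min(a, ncol(Pf))
    res <- Xc - Tf[, seq_len(aa), drop = FALSE] %*% t(Pf[, seq_len(aa), drop = FALSE])
    ss_cal[a] <- sum(res^2)
  }
  list(rmsec = sqrt(ss_cal / (n * k)), rmsecv = sqrt(press / (n * k)))
}

#' Select the number of principal components
#'
#' Takes the smallest component count whose RMSECV is within a relative
#' tolerance of the global RMSECV minimum (parsimony rule: a flat tail of
#' the curve does not buy extra components). The RMSEC curve is checked for
#' monotone non-increase as a sanity condition on the fit.
#'
#' @param rmsec,rmsecv numeric curves of equal length >= 1, indexed by
#'   component count.
#' @param tol relative tolerance on the RMSECV minimum (default 0.01).
#' @return integer A, the selected component count.
#' @export
select_components <- function(rmsec, rmsecv, tol = 0.01) {
  if (length(rmsec) != length(rmsecv) || length(rmsec) < 1L)
    stop("rmsec and rmsecv must have equal length >= 1")
  if (any(diff(rmsec) > 1e-8 * max(rmsec[1L], 1e-12)))
    stop("RMSEC curve is not non-increasing; the calibration fit is inconsistent")
  m <- min(rmsecv)
  as.integer(which(rmsecv <= m * (1 + tol) + 1e-15)[1L])
}

#' Q residuals (squared prediction error)
#'
#' Squared distance of each sample from the A-component model plane:
#' `Q_i = || x_i - x_i P_A P_A' ||^2`. Samples inside the model span have
#' Q = 0; large Q flags variation the model does not describe.
#'
#' @param model a `pca_model`.
#' @param Xc centered block on the model's variable set.
#' @param A component count (defaults to the model's selected A).
#' @return numeric vector of per-sample Q values.
#' @export
q_residuals <- function(model, Xc, A = model$A) {
  if (is.na(A)) stop("no component count selected; pass A or run select_components")
  Xc <- as.matrix(unclass(Xc))
  if (ncol(Xc) != nrow(model$loadings))
    stop("block has ", ncol(Xc), " variables; model expects ", nrow(model$loadings))
  P <- model$loadings[, seq_len(A), drop = FALSE]
  E <- Xc - (Xc %*% P) %*% t(P)
  q <- rowSums(E^2)
  names(q) <- rownames(Xc)
  q
}

#' Hotelling T-squared
#'
#' Variance-normalized squared score distance inside the model plane:
#' `T2_i = sum_{a<=A} t_ia^2 / lambda_a`. On the calibration samples the
#' values sum to `A * (N - 1)` since each eigenvalue is its score column's
#' variance. Large T2 flags high-leverage samples along the principal axes.
#'
#' @param model a `pca_model`.
#' @param Xc centered block (defaults to the calibration data via stored
#'   scores).
#' @param A component count (defaults to the model's selected A).
#' @return numeric vector of per-sample T2 values.
#' @export
hotelling_t2 <- function(model, Xc = NULL, A = model$A) {
  if (is.na(A)) stop("no component count selected; pass A or run select_components")
  lam <- model$eigenvalues[seq_len(A)]
  if (any(lam <= .Machine$double.eps * model$eigenvalues[1L]))
    stop("zero eigenvalue within the selected ", A, " components")
  Tsc <- if (is.null(Xc)) model$scores else {
    Xc <- as.matrix(unclass(Xc))
    if (ncol(Xc) != nrow(model$loadings))
      stop("block has ", ncol(Xc), " variables; model expects ", nrow(model$loadings))
    Xc %*% model$loadings
  }
  t2 <- rowSums(sweep(Tsc[, seq_len(A), drop = FALSE]^2, 2L, lam, "/"))
  names(t2) <- rownames(Tsc)
  t2
}

#' Default configuration for the layered analysis
#'
#' @param a_max maximum components evaluated per class model (default 10,
#'   capped per class by min(N - 1, K) and fold sizes).
#' @param cv_splits venetian-blinds split count (default 10).
#' @param select_tol relative RMSECV tolerance for [select_components()].
#' @param rank_depth how many top-ranked samples per diagnostic count as
#'   flagged (default 3).
#' @param r2_threshold minimum acceptable polyA+ concentration-response R^2
#'   (default 0.95).
#' @param three_five_tolerance maximum acceptable 3'/5' linear-scale ratio
#'   (default 3).
#' @param ma_window moving-average window for [background_curve()].
#' @param cv_scheme held-out reconstruction scheme for
#'   [cross_validate_pca()]: `"elementwise"` (default) or `"rowwise"`.
#' @param random_cv_iter,random_cv_seed iterations and seed of the
#'   random-subset consistency check (0 iterations disables it).
#' @return a named list of settings.
#' @export
qc_config <- function(a_max = 10L, cv_splits = 10L, select_tol = 0.01,
                      rank_depth = 3L, r2_threshold = 0.95,
                      three_five_tolerance = 3, ma_window = 100L,
                      cv_scheme = c("elementwise", "rowwise"),
                      random_cv_iter = 10L, random_cv_seed = 20103349) {
  stopifnot(a_max >= 1L, cv_splits >= 2L, select_tol >= 0, rank_depth >= 1L,
            r2_threshold > 0, three_five_tolerance > 0, ma_window >= 1L)
  list(a_max = as.integer(a_max), cv_splits = as.integer(cv_splits),
       select_tol = select_tol, rank_depth = as.integer(rank_depth),
       r2_threshold = r2_threshold,
       three_five_tolerance = three_five_tolerance,
       ma_window = as.integer(ma_window),
       cv_scheme = match.arg(cv_scheme),
       random_cv_iter = as.integer(random_cv_iter),
       random_cv_seed = random_cv_seed)
}

#' Fit one cross-validated PCA model to a class block
#'
#' Centers the block, assigns venetian-blinds segments with replicate
#' trapping, computes RMSEC/RMSECV, selects the component count, and
#' returns the model with per-sample Q and T2 diagnostics.
#'
#' @param block an [expression_matrix()] restricted to one control class.
#' @param metadata a [hybridization_metadata()] covering the block's rows.
#' @param config a [qc_config()].
#' @return list with `model` (a `pca_model` carrying rmsec/rmsecv/A) and
#'   `diagnostics` (data.frame: hybridization_id, Q, T2, q_rank, t2_rank,
#'   plus per-PC scores).
#' @export
fit_class_model <- function(block, metadata, config = qc_config()) {
  metadata <- align_metadata(block, metadata)
  ctr <- mean_center(block)
  n <- nrow(block); k <- ncol(block)
  splits <- min(config$cv_splits, n)
  assignment <- trap_replicates(venetian_blinds(n, splits), metadata)
  min_train <- min(vapply(unique(assignment),
                          function(s) sum(assignment != s), integer(1L)))
  a_max <- min(config$a_max, n - 1L, k, min_train - 1L)
  cv <- cross_validate_pca(ctr$centered, a_max, assignment,
                           scheme = config$cv_scheme)
  model <- fit_pca(ctr$centered, A_max = a_max, center = ctr$mean)
  model$rmsec <- cv$rmsec
  model$rmsecv <- cv$rmsecv
  model$A <- select_components(cv$rmsec, cv$rmsecv, tol = config$select_tol)
  if (config$random_cv_iter > 0L) {
    model$A_random_cv <- withr_seed(config$random_cv_seed, {
      votes <- replicate(config$random_cv_iter, {
        rs <- trap_replicates(random_subset_assignment(n, splits), metadata)
        ok <- min(vapply(unique(rs), function(s) sum(rs != s), integer(1L))) > a_max
        if (!ok) return(NA_integer_)
        cvr <- cross_validate_pca(ctr$centered, a_max, rs,
                                  scheme = config$cv_scheme)
        select_components(cvr$rmsec, cvr$rmsecv, tol = config$select_tol)
      })
      votes <- votes[!is.na(votes)]
      if (length(votes)) as.integer(names(which.max(table(votes)))) else NA_integer_
    })
  }
  q <- q_residuals(model, ctr$centered)
  t2 <- hotelling_t2(model, ctr$centered)
  diag <- data.frame(hybridization_id = rownames(block),
                     Q = q, T2 = t2,
                     q_rank = rank(-q, ties.method = "first"),
                     t2_rank = rank(-t2, ties.method = "first"),
                     row.names = NULL, stringsAsFactors = FALSE)
  diag <- cbind(diag, as.data.frame(model$scores[, seq_len(model$A), drop = FALSE],
                                    row.names = NULL))
  list(model = model, diagnostics = diag)
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Layered PCA of the four control classes
#'
#' Partitions the matrix by control class and fits one independent
#' cross-validated PCA model per class. Because each control class is added
#' at a different protocol stage, comparing which class models flag a
#' hybridization localizes the stage at which its technical problem arose.
#'
#' @param matrix an [expression_matrix()].
#' @param registry a [control_registry()]; all four classes must be present
#'   in the matrix.
#' @param metadata a [hybridization_metadata()].
#' @param config a [qc_config()].
#' @return named list over the four classes, each a `fit_class_model()`
#'   result.
#' @export
layered_fit <- function(matrix, registry, metadata, config = qc_config()) {
  blocks <- partition_by_class(matrix, registry,
                               require_classes = CONTROL_CLASSES)
  out <- lapply(CONTROL_CLASSES, function(cl) {
    fit_class_model(blocks[[cl]], metadata, config)
  })
  names(out) <- CONTROL_CLASSES
  out
}
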