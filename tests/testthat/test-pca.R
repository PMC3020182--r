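test_that("mean centering zeroes column means and records the offsets", {
  set.seed(2)
  X <- matrix(rnorm(30, 5), 6, 5)
  ctr <- mean_center(X)
  expect_true(all(abs(colMeans(ctr$centered)) < 1e-12))
  expect_equal(ctr$mean, colMeans(X))
  # idempotence on already-centered data
  ctr2 <- mean_center(ctr$centered)
  expect_equal(ctr2$centered, ctr$centered, tolerance = 1e-12)
})

test_that("fit_pca matches an independent eigendecomposition oracle", {
  set.seed(7)
  for (rep in 1:10) {
    X <- matrix(rnorm(24), 6, 4)
    Xc <- mean_center(X)$centered
    model <- fit_pca(Xc, A_max = 3L)
    eig <- eigen(stats::cov(Xc), symmetric = TRUE)  # oracle: covariance route
    expect_equal(model$eigenvalues, eig$values[1:3], tolerance = 1e-8)
    for (a in 1:3) {
      # loadings agree up to sign
      dotp <- abs(sum(model$loadings[, a] * eig$vectors[, a]))
      expect_equal(dotp, 1, tolerance = 1e-8)
    }
    # full-rank reconstruction reproduces Xc
    full <- fit_pca(Xc)
    expect_equal(full$scores %*% t(full$loadings), Xc, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("fit_pca reports variance structure and handles rank deficiency", {
  # rank-1 block: PC1 carries 100% of the variance
  X <- outer(c(1, 2, 3, 4), c(2, -1, 0.5))
  m <- suppressWarnings(fit_pca(mean_center(X)$centered, A_max = 3L))
  expect_equal(m$pct_variance[1L], 100, tolerance = 1e-8)
  expect_warning(fit_pca(mean_center(X)$centered, A_max = 3L), "rank")
  # %variance non-increasing, sums to 100 over full rank
  set.seed(9)
  Xc <- mean_center(matrix(rnorm(50), 10, 5))$centered
  m2 <- fit_pca(Xc)
  expect_true(all(diff(m2$pct_variance) <= 1e-10))
  expect_equal(sum(m2$pct_variance), 100, tolerance = 1e-8)
  expect_true(all(abs(crossprod(m2$loadings) - diag(ncol(m2$loadings))) < 1e-10))
  # score columns mutually orthogonal
  g <- crossprod(m2$scores)
  expect_true(all(abs(g[upper.tri(g)]) < 1e-8))
  # eigenvalue sum equals total column-wise variance
  expect_equal(sum(m2$eigenvalues_all), sum(apply(Xc, 2, var)),
               tolerance = 1e-10)
  expect_error(fit_pca(Xc, A_max = 6L), "A_max")
})

test_that("venetian blinds assigns sample i to segment i mod k", {
  expect_identical(venetian_blinds(10L, 5L),
                   rep(1:5, 2L))
  sizes <- table(venetian_blinds(137L, 10L))
  expect_identical(sort(unique(as.integer(sizes))), c(13L, 14L))
  expect_identical(sum(sizes == 14L), 7L)
  expect_identical(sum(sizes == 13L), 3L)
  expect_error(venetian_blinds(5L, 1L), "splits")
  expect_error(venetian_blinds(5L, 6L), "splits")
})

test_that("replicate trapping moves group members to the first member's segment", {
  md <- toy_metadata(sprintf("H%d", 1:6),
                     groups = c("g1", "g2", "g3", "g1", "g4", "g5"))
  a <- venetian_blinds(6L, 3L)       # 1 2 3 1 2 3
  trapped <- trap_replicates(a, md)
  expect_identical(trapped, c(1L, 2L, 3L, 1L, 2L, 3L))
  md2 <- toy_metadata(sprintf("H%d", 1:6),
                      groups = c("g1", "g1", "g3", "g4", "g5", "g6"))
  trapped2 <- trap_replicates(a, md2)
  expect_identical(trapped2[2L], trapped2[1L])
  expect_identical(trapped2[3:6], a[3:6])
  # singletons leave the assignment unchanged
  expect_identical(trap_replicates(a, toy_metadata(sprintf("H%d", 1:6))), a)
})

test_that("cross-validation recovers exact low-rank structure", {
  set.seed(21)
  # noiseless rank-2 data: two components reconstruct held-out samples
  X <- matrix(rnorm(40), 20, 2) %*% matrix(rnorm(12), 2, 6)
  Xc <- mean_center(X)$centered
  # (rank truncation inside the full-data fit warns; that is the point)
  cv <- suppressWarnings(cross_validate_pca(Xc, 4L, venetian_blinds(20L, 5L)))
  expect_lt(cv$rmsecv[2L], 1e-8)
  # RMSEC vanishes at the full rank
  cv2 <- cross_validate_pca(mean_center(matrix(rnorm(40), 10, 4))$centered,
                            3L, venetian_blinds(10L, 5L))
  full <- cross_validate_pca(mean_center(matrix(rnorm(24), 8, 3))$centered,
                             3L, venetian_blinds(8L, 4L))
  expect_lt(full$rmsec[3L], 1e-10)
  # a fold whose training set is smaller than A_max + 1 is rejected by name
  expect_error(cross_validate_pca(Xc[1:12, ], 7L, venetian_blinds(12L, 2L)),
               "training fold")
})

test_that("venetian-blinds and random-subset CV agree on A for well-separated spectra", {
  agree <- 0L
  for (rep in 1:20) {
    set.seed(100 + rep)
    n <- 40L; k <- 8L
    scores <- cbind(rnorm(n, 0, 8), rnorm(n, 0, 5), rnorm(n, 0, 3))
    load <- qr.Q(qr(matrix(rnorm(k * 3), k, 3)))
    X <- scores %*% t(load) + matrix(rnorm(n * k, 0, 0.05), n, k)
    Xc <- mean_center(X)$centered
    cv_v <- cross_validate_pca(Xc, 6L, venetian_blinds(n, 10L))
    a_v <- select_components(cv_v$rmsec, cv_v$rmsecv)
    cv_r <- cross_validate_pca(Xc, 6L, random_subset_assignment(n, 10L))
    a_r <- select_components(cv_r$rmsec, cv_r$rmsecv)
    agree <- agree + (a_v == a_r)
    expect_equal(a_v, 3L)
  }
  expect_gte(agree, 18L)
})

test_that("component selection applies the parsimony rule and checks RMSEC sanity", {
  expect_identical(select_components(c(3, 2, 1, 1), c(5, 3, 1, 2)), 3L)
  # flat beyond a = 2 within tolerance
  expect_identical(select_components(c(3, 2, 1.5, 1), c(5, 1.004, 1.002, 1.0)), 2L)
  expect_identical(select_components(2, 3), 1L)
  expect_error(select_components(c(1, 2), c(2, 1)), "non-increasing")
  expect_error(select_components(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("Q residuals measure the orthogonal distance to the model plane", {
  # hand case: x = (3, 4), single loading (1, 0): residual is (0, 4), Q = 16
  model <- structure(list(loadings = matrix(c(1, 0), 2, 1),
                          eigenvalues = 1, A = 1L, N = 3L, K = 2L),
                     class = "pca_model")
  expect_equal(unname(q_residuals(model, matrix(c(3, 4), 1, 2))), 16)
  # samples inside the span have Q = 0; at A = rank all calibration Q = 0
  set.seed(31)
  Xc <- mean_center(matrix(rnorm(36), 9, 4))$centered
  m <- fit_pca(Xc)
  expect_true(all(q_residuals(m, Xc, A = m$rank) < 1e-16))
  inplane <- matrix(m$loadings[, 1L] * 2.5, 1)
  expect_lt(q_residuals(m, inplane, A = 1L), 1e-20)
  expect_error(q_residuals(m, Xc[, 1:3], A = 1L), "variables")
})

test_that("Q plus within-plane energy decomposes the total sum of squares", {
  set.seed(33)
  Xc <- mean_center(matrix(rnorm(60), 12, 5))$centered
  m <- fit_pca(Xc)
  for (A in 1:4) {
    inspan <- rowSums((Xc %*% m$loadings[, 1:A, drop = FALSE])^2)
    expect_equal(sum(inspan) + sum(q_residuals(m, Xc, A = A)),
                 sum(Xc^2), tolerance = 1e-10)
  }
})

test_that("Hotelling T2 follows the direct formula and its calibration identity", {
  # 1-PC toy with scores (-1, 0, 1): lambda = 1, so T2 = t^2 / lambda
  model <- structure(list(loadings = matrix(c(1, 0), 2, 1),
                          scores = matrix(c(-1, 0, 1), 3, 1),
                          eigenvalues = 1, A = 1L, N = 3L, K = 2L),
                     class = "pca_model")
  expect_equal(unname(hotelling_t2(model)), c(1, 0, 1))
  # sample at the calibration mean scores zero
  set.seed(41)
  Xc <- mean_center(matrix(rnorm(70), 14, 5))$centered
  m <- fit_pca(Xc)
  expect_equal(unname(hotelling_t2(m, matrix(0, 1, 5), A = 2L)), 0)
  # sum over calibration samples is A * (N - 1)
  for (A in 1:3)
    expect_equal(sum(hotelling_t2(m, Xc, A = A)), A * (m$N - 1),
                 tolerance = 1e-10)
})

test_that("layered fit produces one model per class and localizes a labeling failure", {
  sim <- simulate_experiment(default_rae230a_scenario(seed = 6L))
  fits <- layered_fit(sim$matrix, sim$registry, sim$metadata, fast_config())
  expect_named(fits, c("hybridization", "polyA", "rna_degradation",
                       "endogenous"))
  lab <- sim$truth$hybridization_id[sim$truth$anomaly == "labeling_failure"]
  dpa <- fits$polyA$diagnostics
  dh <- fits$hybridization$diagnostics
  expect_identical(dpa$hybridization_id[dpa$t2_rank == 1L], lab)
  expect_gt(dh$t2_rank[dh$hybridization_id == lab], 1L)
})
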