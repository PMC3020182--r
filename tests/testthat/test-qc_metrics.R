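test_that("polyA correlation scores the concentration response", {
  design <- rae230a_spikein_design()
  lc <- log2(design$concentrations)
  # exactly linear signal: R^2 = 1
  r2 <- polya_correlation(2 + 0.9 * lc, design)
  expect_equal(as.numeric(r2), 1, tolerance = 1e-12)
  expect_false(attr(r2, "degenerate"))
  # affine rescaling leaves R^2 unchanged
  set.seed(3)
  sig <- 2 + lc + rnorm(5, 0, 0.4)
  expect_equal(as.numeric(polya_correlation(sig, design)),
               as.numeric(polya_correlation(3 * sig - 7, design)),
               tolerance = 1e-12)
  # constant signal: degenerate, reported as zero
  r0 <- polya_correlation(setNames(rep(5, 5), names(lc)), design)
  expect_equal(as.numeric(r0), 0)
  expect_true(attr(r0, "degenerate"))
  expect_error(polya_correlation(c(Lys = 1, Phe = 2), design), "3 transcripts")
})

test_that("the printed outlier difference profile is linear in log2 concentration", {
  design <- rae230a_spikein_design()
  diffs <- difference_profile(table2_experiment_means, table2_outlier_values)
  expect_equal(diffs[["Lys"]], 7.21, tolerance = 1e-12)
  expect_equal(diffs[["Dap"]], 3.58, tolerance = 1e-12)
  expect_true(as.numeric(polya_correlation(diffs, design)) >= 0.95)
  # identical inputs give a zero profile; mismatched sets error
  expect_equal(unname(difference_profile(table2_experiment_means,
                                         table2_experiment_means)),
               rep(0, 5))
  expect_error(difference_profile(table2_experiment_means,
                                  table2_experiment_means[-1L]), "differ")
})

test_that("3'/5' ratio converts the log2 difference to the linear scale", {
  expect_equal(three_prime_five_prime_ratio(4.2, 4.2), 1)
  expect_equal(three_prime_five_prime_ratio(6, 4), 4)
  # monotone increasing in the log2 difference
  d <- seq(-2, 4, by = 0.5)
  expect_true(all(diff(three_prime_five_prime_ratio(d, 0)) > 0))
  # a ratio of 3.16 exceeds the conventional tolerance of 3
  expect_gt(three_prime_five_prime_ratio(log2(3.16), 0), 3)
  expect_error(three_prime_five_prime_ratio(Inf, 1))
})

test_that("ordering check flags exactly the printed Dap/Thr inversion", {
  design <- rae230a_spikein_design()
  v <- ordering_check(table2_experiment_means, design$expected_order)
  expect_identical(nrow(v), 1L)
  expect_identical(v$higher, "Dap")
  expect_identical(v$lower, "Thr")
  expect_equal(v$higher_value, 7.91)
  expect_equal(v$lower_value, 8.00)
  # strictly decreasing signals pass; ties are violations
  ok <- setNames(c(5, 4, 3, 2, 1), design$expected_order)
  expect_identical(nrow(ordering_check(ok, design$expected_order)), 0L)
  tie <- ok; tie[2L] <- 5
  expect_identical(nrow(ordering_check(tie, design$expected_order)), 1L)
  expect_error(ordering_check(ok[-1L], design$expected_order), "missing")
})

test_that("transcript signals summarize probesets and drive per-array metrics", {
  sim <- simulate_experiment(default_rae230a_scenario(seed = 2L))
  blocks <- partition_by_class(sim$matrix, sim$registry)
  sig <- transcript_signals(blocks$polyA, sim$registry)
  expect_setequal(colnames(sig), c("Lys", "Phe", "Thr", "Dap", "Trp"))
  sig3 <- transcript_signals(blocks$polyA, sim$registry, method = "three_prime")
  # 3'-only summaries sit above the all-position mean (5' attenuation)
  expect_true(mean(sig3 - sig) > 0)
  met <- compute_qc_metrics(sim$matrix, sim$registry, sim$design)
  expect_setequal(names(met$polya_r2), rownames(sim$matrix))
})

test_that("flag aggregation attributes anomalies to the earliest implicated stage", {
  ids <- c("clean1", "polya_only", "everywhere")
  mk_model <- function() structure(list(N = 3L, A = 1L, eigenvalues = 1,
                                        eigenvalues_all = c(1, 0.5)),
                                   class = "pca_model")
  mk_diag <- function(t2) data.frame(hybridization_id = ids, Q = c(0, 0, 0),
                                     T2 = t2,
                                     q_rank = rank(-c(0, 0, 0), ties.method = "first"),
                                     t2_rank = rank(-t2, ties.method = "first"))
  fits <- list(
    hybridization = list(model = mk_model(), diagnostics = mk_diag(c(0.1, 0.2, 80))),
    polyA = list(model = mk_model(), diagnostics = mk_diag(c(0.1, 90, 80))),
    rna_degradation = list(model = mk_model(), diagnostics = mk_diag(c(0.1, 0.2, 80))),
    endogenous = list(model = mk_model(), diagnostics = mk_diag(c(0.1, 0.2, 80))))
  metrics <- list(
    polya_r2 = setNames(c(0.99, 0.40, 0.99), ids),
    degenerate = setNames(rep(FALSE, 3), ids),
    ratios = data.frame(hybridization_id = ids, class = "rna_degradation",
                        transcript = "GAPDH", ratio = c(1.2, 1.4, 1.1)),
    ordering = data.frame(hybridization_id = character(0),
                          higher = character(0), lower = character(0),
                          higher_value = numeric(0), lower_value = numeric(0)))
  cfg <- qc_config(rank_depth = 2L)
  rep <- aggregate_qc(fits, metrics, cfg)
  tab <- rep$table
  expect_identical(tab$stage[tab$hybridization_id == "clean1"], "none")
  expect_identical(tab$stage[tab$hybridization_id == "polya_only"],
                   "amplification/labeling")
  expect_identical(tab$stage[tab$hybridization_id == "everywhere"],
                   "hybridization/scanning")
  expect_true(tab$multi_class[tab$hybridization_id == "everywhere"])
  expect_false(any(rep$flags$hybridization_id == "clean1"))
  # every flag carries its triggering value and threshold
  expect_true(all(c("value", "threshold") %in% colnames(rep$flags)))
  # missing hybridization in the metric results errors
  metrics_bad <- metrics
  metrics_bad$polya_r2 <- metrics_bad$polya_r2[-1L]
  expect_error(aggregate_qc(fits, metrics_bad, cfg), "missing")
})
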