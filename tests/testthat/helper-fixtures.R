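# Small fixtures shared across test files; all generated in code.

toy_matrix <- function(n = 2L, k = 3L, seed = 42L) {
  set.seed(seed)
  expression_matrix(matrix(round(rnorm(n * k, 8, 1), 3), n, k,
                           dimnames = list(sprintf("H%02d", seq_len(n)),
                                           sprintf("ps%03d", seq_len(k)))))
}

toy_metadata <- function(ids, groups = NULL) {
  hybridization_metadata(data.frame(
    hybridization_id = ids,
    date_class = "A",
    replicate_group = if (is.null(groups)) paste0("rg_", ids) else groups,
    stringsAsFactors = FALSE))
}

# a config that skips the random-subset consistency check (speed)
fast_config <- function(...) qc_config(random_cv_iter = 0L, ...)

# Table 2 printed columns: concentrations live in rae230a_spikein_design();
# these are the printed per-transcript RMA summaries.
table2_experiment_means <- c(Trp = 4.69, Thr = 8.00, Dap = 7.91,
                             Phe = 10.23, Lys = 11.82)
table2_outlier_values <- c(Trp = 4.26, Thr = 5.06, Dap = 4.33,
                           Phe = 4.80, Lys = 4.61)
table2_differences <- c(Trp = 0.43, Thr = 2.94, Dap = 3.58,
                        Phe = 5.43, Lys = 7.21)
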