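#' Run the full control-QC pipeline
#'
#' Executes normalization, the mean/SD dispersion screen, the layered
#' per-class PCA with cross-validated component selection, the scalar
#' spike-in/degradation metrics, and flag aggregation. Inputs may be given
#' as objects or file paths. Given the same inputs, configuration and seed
#' the result is identical.
#'
#' @param matrix an [expression_matrix()] or path to a TSV/CSV (probesets
#'   in rows).
#' @param registry a [control_registry()] or TSV path; defaults to the
#'   built-in RAE230A registry.
#' @param metadata a [hybridization_metadata()] or TSV path.
#' @param design a [spikein_design()]; defaults to the RAE230A polyA+
#'   design.
#' @param config a [qc_config()].
#' @param normalization `"p75"`, `"quantile"` or `"none"`.
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `report.tsv`, `flags.tsv`, `dispersion.tsv` and per-class
#'   `scores_<class>.tsv`, `loadings_<class>.tsv`, `diagnostics_<class>.tsv`.
#' @return list with `report` (a `qc_report`), `fits` (per-class models and
#'   diagnostics), `metrics`, `dispersion` (the mean/SD table), and
#'   `normalized` (the matrix the models were fitted on).
#' @export
run_pipeline <- function(matrix, registry = build_rae230a_registry(),
                         metadata, design = rae230a_spikein_design(),
                         config = qc_config(),
                         normalization = c("p75", "quantile", "none"),
                         out_dir = NULL) {
  normalization <- match.arg(normalization)
  if (is.character(matrix)) matrix <- read_expression_matrix(matrix)
  if (is.character(registry)) registry <- read_registry(registry)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  metadata <- align_metadata(matrix, metadata)

  message("stage: normalize (", normalization, ")")
  norm <- tryCatch(normalize_matrix(matrix, normalization, registry = registry),
                   error = function(e) stop("normalize stage failed: ",
                                            conditionMessage(e), call. = FALSE))
  message("stage: dispersion")
  disp <- tryCatch(mean_sd_table(norm, registry),
                   error = function(e) stop("dispersion stage failed: ",
                                            conditionMessage(e), call. = FALSE))
  message("stage: layered PCA")
  fits <- tryCatch(layered_fit(norm, registry, metadata, config),
                   error = function(e) stop("layered_pca stage failed: ",
                                            conditionMessage(e), call. = FALSE))
  message("stage: qc metrics")
  metrics <- tryCatch(compute_qc_metrics(norm, registry, design, config),
                      error = function(e) stop("qc_metrics stage failed: ",
                                               conditionMessage(e), call. = FALSE))
  message("stage: aggregate")
  report <- tryCatch(aggregate_qc(fits, metrics, config),
                     error = function(e) stop("aggregate stage failed: ",
                                              conditionMessage(e), call. = FALSE))

  if (!is.null(out_dir)) write_pipeline_outputs(report, fits, disp, out_dir)
  list(report = report, fits = fits, metrics = metrics,
       dispersion = disp, normalized = norm)
}

#' Serialize a QC report to a versioned JSON structure
#'
#' @param report a `qc_report`.
#' @param fits optional [layered_fit()] result for per-class model
#'   summaries.
#' @return a list ready for [jsonlite::write_json()].
#' @export
report_to_json <- function(report, fits = NULL) {
  out <- list(schema_version = "1.0",
              generator = "controlqc",
              config = report$config,
              hybridizations = report$table,
              flags = report$flags)
  if (!is.null(fits)) {
    out$models <- lapply(fits, function(f) {
      m <- f$model
      list(N = m$N, K = m$K, A = m$A,
           cum_pct_variance_at_A = m$cum_pct_variance[m$A],
           rmsec = m$rmsec, rmsecv = m$rmsecv)
    })
  }
  out
}

write_pipeline_outputs <- function(report, fits, disp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_json(report, fits),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$table, file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$flags, file.path(out_dir, "flags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(disp, file.path(out_dir, "dispersion.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cl in names(fits)) {
    m <- fits[[cl]]$model
    utils::write.table(data.frame(hybridization_id = rownames(m$scores),
                                  m$scores, check.names = FALSE),
                       file.path(out_dir, paste0("scores_", cl, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(probeset_id = rownames(m$loadings),
                                  m$loadings, check.names = FALSE),
                       file.path(out_dir, paste0("loadings_", cl, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fits[[cl]]$diagnostics,
                       file.path(out_dir, paste0("diagnostics_", cl, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
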