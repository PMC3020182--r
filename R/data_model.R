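# Control classes recognised throughout the package, in protocol-stage order
# (earliest wet-lab stage last): hybridization controls are added last, so an
# anomaly visible there implicates the hybridization/scanning stage.
CONTROL_CLASSES <- c("hybridization", "polyA", "rna_degradation", "endogenous")

#' Construct an expression matrix object
#'
#' An expression matrix holds log2 probeset-level summaries (e.g. RMA output)
#' for N hybridizations by K probesets. In memory the orientation is
#' N x K (hybridizations in rows); on disk the conventional orientation is
#' probesets in rows, hybridizations in columns.
#'
#' @param values numeric matrix, N hybridizations x K probesets.
#' @param hybridization_ids,probeset_ids optional character vectors; taken
#'   from `dimnames(values)` when omitted.
#' @param log2_scale logical marker recording that values are log2.
#' @return an `expression_matrix`: the numeric matrix with row/column names
#'   and attribute `log2_scale`.
#' @export
expression_matrix <- function(values, hybridization_ids = rownames(values),
                              probeset_ids = colnames(values),
                              log2_scale = TRUE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix must have at least one hybridization and one probeset")
  if (is.null(hybridization_ids) || is.null(probeset_ids))
    stop("hybridization and probeset identifiers are required")
  hybridization_ids <- as.character(hybridization_ids)
  probeset_ids <- as.character(probeset_ids)
  if (anyDuplicated(hybridization_ids))
    stop("duplicate hybridization IDs: ",
         paste(unique(hybridization_ids[duplicated(hybridization_ids)]), collapse = ", "))
  if (anyDuplicated(probeset_ids))
    stop("duplicate probeset IDs: ",
         paste(unique(probeset_ids[duplicated(probeset_ids)]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at hybridization '%s', probeset '%s'",
                 hybridization_ids[bad[1L]], probeset_ids[bad[2L]]))
  }
  dimnames(values) <- list(hybridization_ids, probeset_ids)
  structure(values, log2_scale = isTRUE(log2_scale),
            class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d hybridizations x %d probesets (log2=%s)\n",
              nrow(x), ncol(x), isTRUE(attr(x, "log2_scale"))))
  invisible(x)
}

#' Read an expression matrix from a delimited text file
#'
#' Expects probesets in rows and hybridizations in columns: the first column
#' holds probeset IDs and the header row holds hybridization IDs. The matrix
#' is transposed to the in-memory N x K orientation.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param sep field separator; `"\t"` or `","`.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("expression matrix needs an ID column plus at least one hybridization")
  probeset_ids <- tab[[1L]]
  hyb_ids <- colnames(tab)[-1L]
  body <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing value at probeset '%s', hybridization '%s'",
                 probeset_ids[bad[1L]], hyb_ids[bad[2L]]))
  }
  dimnames(num) <- list(probeset_ids, hyb_ids)
  expression_matrix(t(num))
}

#' Write an expression matrix to a delimited text file
#'
#' Writes in the on-disk convention (probesets in rows).
#'
#' @param matrix an [expression_matrix()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_expression_matrix <- function(matrix, path, sep = "\t") {
  stopifnot(inherits(matrix, "expression_matrix"))
  disk <- t(unclass(matrix))
  df <- data.frame(probeset_id = rownames(disk), disk,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a control-class registry
#'
#' @param entries data.frame with columns `probeset_id`, `class` (one of
#'   hybridization, polyA, rna_degradation, endogenous), `transcript`,
#'   `position` (one of `5'`, `M`, `3'`, `none`), `revision` (one of
#'   `original`, `r2`, `none`).
#' @return a `control_registry` data.frame.
#' @export
control_registry <- function(entries) {
  needed <- c("probeset_id", "class", "transcript", "position", "revision")
  if (!all(needed %in% colnames(entries)))
    stop("registry needs columns: ", paste(needed, collapse = ", "))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)[, needed]
  if (anyDuplicated(entries$probeset_id))
    stop("a probeset maps to more than one registry entry: ",
         paste(unique(entries$probeset_id[duplicated(entries$probeset_id)]), collapse = ", "))
  bad_class <- setdiff(unique(entries$class), CONTROL_CLASSES)
  if (length(bad_class))
    stop("unknown control class: ", paste(bad_class, collapse = ", "))
  bad_pos <- setdiff(unique(entries$position), c("5'", "M", "3'", "none"))
  if (length(bad_pos))
    stop("unknown position tag: ", paste(bad_pos, collapse = ", "))
  structure(entries, class = c("control_registry", "data.frame"))
}

#' Read a control registry from TSV
#'
#' @param path TSV with columns probeset_id, class, transcript, position,
#'   revision.
#' @return a [control_registry()].
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  control_registry(utils::read.table(path, sep = "\t", header = TRUE,
                                     colClasses = "character", quote = "\"",
                                     comment.char = ""))
}

#' Write a control registry to TSV
#' @param registry a [control_registry()].
#' @param path output path.
#' @export
write_registry <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Built-in RAE230A control registry
#'
#' The standard Affymetrix control complement of the RAE230A array, named in
#' the AFFX convention and split into the four control classes:
#' \itemize{
#'   \item hybridization: biotinylated BioB (5'/M/3'), BioC (5'/3'),
#'     BioDn (5'/3') and CreX (5'/3') spike-ins, in original and r2 probe
#'     set revisions (18 probesets);
#'   \item polyA: B. subtilis Lys, Phe, Thr, Dap transcripts at 5'/M/3'
#'     positions in two revisions, plus Trp at 5'/M/3' (27 probesets);
#'   \item rna_degradation: GAPDH and beta-Actin at 5'/M/3' in two revisions
#'     (12 probesets);
#'   \item endogenous: a 100-gene housekeeping list. The authoritative gene
#'     identities are array-annotation specific; the packaged default is a
#'     synthetic placeholder list of 100 IDs (see
#'     `system.file("extdata", "rae230a_endogenous_synthetic.tsv",
#'     package = "controlqc")`) that preserves the documented class size.
#' }
#'
#' @param endogenous_path optional TSV overriding the endogenous list; same
#'   columns as [read_registry()].
#' @return a [control_registry()] with class sizes 18, 27, 12, 100.
#' @export
build_rae230a_registry <- function(endogenous_path = NULL) {
  pos3 <- c("5'", "M", "3'")
  pos2 <- c("5'", "3'")
  revs <- c("original", "r2")

  hyb_tx <- list(BioB = pos3, BioC = pos2, BioDn = pos2, CreX = pos2)
  hyb <- do.call(rbind, lapply(names(hyb_tx), function(tx) {
    expand.grid(transcript = tx, position = hyb_tx[[tx]], revision = revs,
                stringsAsFactors = FALSE)
  }))
  hyb$class <- "hybridization"

  polya <- expand.grid(transcript = c("Lys", "Phe", "Thr", "Dap"),
                       position = pos3, revision = revs,
                       stringsAsFactors = FALSE)
  trp <- expand.grid(transcript = "Trp", position = pos3, revision = "original",
                     stringsAsFactors = FALSE)
  polya <- rbind(polya, trp)
  polya$class <- "polyA"

  rnad <- expand.grid(transcript = c("GAPDH", "bActin"), position = pos3,
                      revision = revs, stringsAsFactors = FALSE)
  rnad$class <- "rna_degradation"

  ctrl <- rbind(hyb[, c("class", "transcript", "position", "revision")],
                polya[, c("class", "transcript", "position", "revision")],
                rnad[, c("class", "transcript", "position", "revision")])
  pos_tag <- c("5'" = "5", "M" = "M", "3'" = "3")[ctrl$position]
  rev_tag <- ifelse(ctrl$revision == "r2", "AFFX-r2-", "AFFX-")
  ctrl$probeset_id <- paste0(rev_tag, ctrl$transcript, "-", pos_tag, "_at")

  if (is.null(endogenous_path))
    endogenous_path <- system.file("extdata", "rae230a_endogenous_synthetic.tsv",
                                   package = "controlqc")
  endo <- utils::read.table(endogenous_path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "\"",
                            comment.char = "")
  control_registry(rbind(
    ctrl[, c("probeset_id", "class", "transcript", "position", "revision")],
    endo[, c("probeset_id", "class", "transcript", "position", "revision")]))
}

#' Class sizes of a registry
#' @param registry a [control_registry()].
#' @return named integer vector over the four control classes.
#' @export
registry_class_sizes <- function(registry) {
  vapply(CONTROL_CLASSES,
         function(cl) sum(registry$class == cl), integer(1L))
}

#' Partition an expression matrix by control class
#'
#' Splits the K probesets into the four control-class blocks plus a
#' `background` block holding every probeset not present in the registry
#' (the non-control complement).
#'
#' @param matrix an [expression_matrix()].
#' @param registry a [control_registry()].
#' @param require_classes character vector of classes that must be non-empty
#'   in the result; defaults to none.
#' @return named list of [expression_matrix()] blocks:
#'   hybridization, polyA, rna_degradation, endogenous, background. Classes
#'   with no matching probesets are dropped unless required (then an error).
#' @export
partition_by_class <- function(matrix, registry,
                               require_classes = character(0)) {
  stopifnot(inherits(matrix, "expression_matrix"))
  ids <- colnames(matrix)
  cls <- registry$class[match(ids, registry$probeset_id)]
  cls[is.na(cls)] <- "background"
  out <- list()
  for (cl in c(CONTROL_CLASSES, "background")) {
    keep <- which(cls == cl)
    if (length(keep))
      out[[cl]] <- expression_matrix(unclass(matrix)[, keep, drop = FALSE],
                                     log2_scale = attr(matrix, "log2_scale"))
  }
  missing <- setdiff(require_classes, names(out))
  if (length(missing))
    stop("no probesets found for control class(es): ",
         paste(missing, collapse = ", "))
  out
}

#' Read hybridization metadata
#'
#' @param path TSV with columns hybridization_id, date_class,
#'   replicate_group and optional scan_qc (ordinal 1-4).
#' @return a `hybridization_metadata` data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  hybridization_metadata(utils::read.table(path, sep = "\t", header = TRUE,
                                           colClasses = "character",
                                           quote = "\"", comment.char = ""))
}

#' Construct hybridization metadata
#' @param entries data.frame with columns hybridization_id, date_class,
#'   replicate_group, optionally scan_qc.
#' @return a `hybridization_metadata` data.frame.
#' @export
hybridization_metadata <- function(entries) {
  needed <- c("hybridization_id", "date_class", "replicate_group")
  if (!all(needed %in% colnames(entries)))
    stop("metadata needs columns: ", paste(needed, collapse = ", "))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!"scan_qc" %in% colnames(entries)) entries$scan_qc <- NA
  if (anyDuplicated(entries$hybridization_id))
    stop("duplicate hybridization_id in metadata")
  if (any(is.na(entries$replicate_group) | entries$replicate_group == ""))
    stop("replicate_group must be non-missing for every hybridization")
  structure(entries[, c(needed, "scan_qc")],
            class = c("hybridization_metadata", "data.frame"))
}

#' Write hybridization metadata to TSV
#' @param metadata a [hybridization_metadata()].
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that metadata covers a matrix
#' @param matrix an [expression_matrix()].
#' @param metadata a [hybridization_metadata()].
#' @return metadata reordered to the matrix's hybridizations (invisibly
#'   errors when one is missing).
#' @export
align_metadata <- function(matrix, metadata) {
  idx <- match(rownames(matrix), metadata$hybridization_id)
  if (anyNA(idx))
    stop("metadata missing for hybridization(s): ",
         paste(rownames(matrix)[is.na(idx)], collapse = ", "))
  metadata[idx, , drop = FALSE]
}

#' Spike-in concentration design
#'
#' @param concentrations named numeric vector, transcript -> concentration
#'   in ng/uL; strictly positive.
#' @param expected_order character vector ranking transcripts by expected
#'   signal (highest first); must be a permutation of the transcripts.
#' @return a `spikein_design` list.
#' @export
spikein_design <- function(concentrations, expected_order = NULL) {
  if (is.null(names(concentrations)) || any(names(concentrations) == ""))
    stop("concentrations must be a named vector")
  if (any(concentrations <= 0)) stop("concentrations must be strictly positive")
  if (is.null(expected_order))
    expected_order <- names(sort(concentrations, decreasing = TRUE))
  if (!setequal(expected_order, names(concentrations)) ||
      length(expected_order) != length(concentrations))
    stop("expected_order must be a permutation of the transcripts")
  structure(list(concentrations = concentrations,
                 expected_order = expected_order),
            class = "spikein_design")
}

#' Standard RAE230A polyA+ spike-in design
#'
#' The five B. subtilis polyA+ transcripts with their spike concentrations
#' (ng/uL): Trp 14.7, Thr 39.1, Dap 108.9, Phe 260.0, Lys 591.1. Expected
#' signal ordering Lys > Phe > Dap > Thr > Trp.
#'
#' @return a [spikein_design()].
#' @export
rae230a_spikein_design <- function() {
  spikein_design(
    c(Trp = 14.7, Thr = 39.1, Dap = 108.9, Phe = 260.0, Lys = 591.1),
    expected_order = c("Lys", "Phe", "Dap", "Thr", "Trp"))
}
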