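#' Write / read a counts matrix as (gzip) TSV
#'
#' Genes in rows with a leading `gene` column, samples in the header row.
#' A `.gz` suffix selects gzip compression transparently in both directions.
#'
#' @param counts Numeric matrix with gene rownames and sample colnames.
#' @param path Output path (`.tsv` or `.tsv.gz`).
#' @return `read_counts_tsv` returns the numeric matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

must_exist <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input file not found: '%s'", path), call. = FALSE)
  path
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(must_exist(path), check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Read a counts matrix from an MTX triplet
#'
#' MatrixMarket sparse matrix plus one-id-per-line row (gene) and column
#' (sample) files.
#'
#' @param mtx,rows_path,cols_path Paths to the triplet.
#' @return Dense numeric matrix with dimnames.
#' @export
read_counts_mtx <- function(mtx, rows_path, cols_path) {
  m <- as.matrix(Matrix::readMM(mtx))
  rownames(m) <- readLines(rows_path, warn = FALSE)
  colnames(m) <- readLines(cols_path, warn = FALSE)
  m
}

#' Write / read per-sample group labels
#'
#' Two-column TSV `sample_id`, `group` with group in case/control.
#'
#' @param group Character/factor vector named by sample, or unnamed with
#'   `sample_ids` given.
#' @param sample_ids Sample identifiers (defaults to `names(group)`).
#' @param path File path.
#' @return `read_group_labels` returns a named character vector.
#' @export
write_group_labels <- function(group, path, sample_ids = names(group)) {
  utils::write.table(
    data.frame(sample_id = sample_ids, group = as.character(group),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_group_labels
#' @export
read_group_labels <- function(path) {
  df <- utils::read.delim(must_exist(path), stringsAsFactors = FALSE)
  stats::setNames(as.character(df$group), df$sample_id)
}

#' Read an expression matrix plus labels into an [expression_matrix()]
#'
#' @param counts_path TSV/TSV.gz counts path.
#' @param labels_path Group-label TSV path.
#' @return An [expression_matrix()] with columns ordered as in the counts
#'   file.
#' @export
read_expression_matrix <- function(counts_path, labels_path) {
  counts <- read_counts_tsv(counts_path)
  labels <- read_group_labels(labels_path)
  missing_lab <- setdiff(colnames(counts), names(labels))
  if (length(missing_lab))
    stop(sprintf("no group label for sample(s): %s",
                 paste(utils::head(missing_lab, 5), collapse = ", ")),
         call. = FALSE)
  expression_matrix(counts, labels[colnames(counts)])
}

#' Write / read a study DE table
#'
#' TSV with header `gene`, `log2fc`, `pvalue`, `padj`, `direction`.
#'
#' @param result A `study_de_result`.
#' @param path File path.
#' @export
write_de_table <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a consensus signature as TSV
#'
#' Columns `gene`, `direction`, `support`, `summary_lfc`, `conflicted`.
#'
#' @param cs A `consensus_signature`.
#' @param path File path.
#' @export
write_consensus <- function(cs, path) {
  utils::write.table(as.data.frame(cs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' @param truth A `synthetic_truth`.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(
    signature = truth$signature,
    per_study_active = lapply(
      stats::setNames(seq_len(nrow(truth$per_study_active)),
                      rownames(truth$per_study_active)),
      function(i) colnames(truth$per_study_active)[truth$per_study_active[i, ]]),
    universe = truth$universe,
    model_active = truth$model_active)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Study manifest handling
#'
#' A study manifest is a TSV with one row per study and columns `study_id`,
#' `n_young`, `n_old`, optional age-range and tissue annotations, and
#' optional paths to the study's counts/labels or DE table. The packaged
#' example `inst/extdata/human_studies_manifest.tsv` transcribes the
#' five-study human muscle-aging design (old vs young vastus lateralis
#' biopsies).
#'
#' @param path Manifest TSV path.
#' @return `read_manifest` returns a validated data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(must_exist(path), stringsAsFactors = FALSE)
  if (!all(c("study_id", "n_young", "n_old") %in% names(m)))
    stop("manifest needs columns 'study_id', 'n_young', 'n_old'",
         call. = FALSE)
  if (anyDuplicated(m$study_id))
    stop("duplicate study_id in manifest", call. = FALSE)
  if (nrow(m) && any(m$n_young < 0 | m$n_old < 0))
    stop("participant counts must be non-negative", call. = FALSE)
  m
}

#' @rdname read_manifest
#' @param manifest A manifest data frame from `read_manifest`.
#' @return `summarize_manifest` returns a list with `n_studies`,
#'   `total_young`, `total_old` (column sums over studies).
#' @export
summarize_manifest <- function(manifest) {
  if (nrow(manifest) && any(manifest$n_young < 0 | manifest$n_old < 0))
    stop("participant counts must be non-negative", call. = FALSE)
  list(n_studies = nrow(manifest),
       total_young = sum(manifest$n_young),
       total_old = sum(manifest$n_old))
}
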