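#' Log2 counts-per-million transformation
#'
#' `value(g,s) = log2(1e6 * count(g,s) / libsize(s) + pseudocount)` with the
#' library size taken as the raw column sum.
#'
#' @param x An [expression_matrix()] or a numeric matrix of counts.
#' @param pseudocount Positive offset added after CPM scaling.
#' @return Object of the same kind as `x` with transformed values.
#' @export
log_cpm <- function(x, pseudocount = 1) UseMethod("log_cpm")

#' @export
log_cpm.expression_matrix <- function(x, pseudocount = 1) {
  x$values <- log_cpm(x$values, pseudocount)
  x
}

#' @export
log_cpm.default <- function(x, pseudocount = 1) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix", call. = FALSE)
  if (pseudocount <= 0) stop("'pseudocount' must be positive", call. = FALSE)
  libsize <- colSums(x)
  bad <- which(libsize <= 0)
  if (length(bad))
    stop(sprintf("zero library size for sample(s): %s",
                 paste(colnames(x)[bad], collapse = ", ")), call. = FALSE)
  log2(sweep(x, 2L, 1e6 / libsize, "*") + pseudocount)
}

#' Vectorised two-sided Welch's t-test per gene
#'
#' For every row of a transformed matrix, computes the case-minus-control mean
#' difference (the log2 fold change on the log-CPM scale), the Welch t
#' statistic with Welch-Satterthwaite degrees of freedom, and the two-sided
#' p-value. When both group variances are zero the p-value is 1 if the means
#' are equal and the smallest representable positive double otherwise.
#'
#' @param x Numeric matrix (genes x samples), typically log2-CPM.
#' @param group Case/control label per column.
#' @return Data frame with columns `gene`, `log2fc`, `pvalue`.
#' @export
welch_test <- function(x, group) {
  if (inherits(x, "expression_matrix")) {
    group <- x$group
    x <- x$values
  }
  group <- as.character(group)
  if (length(group) != ncol(x))
    stop("one group label per column is required", call. = FALSE)
  case <- x[, group == "case", drop = FALSE]
  ctrl <- x[, group == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples for Welch's t", call. = FALSE)
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  tstat <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degen <- se2 == 0
  p[degen] <- ifelse(diff[degen] == 0, 1, .Machine$double.xmin)
  tstat[degen] <- ifelse(diff[degen] == 0, 0, Inf * sign(diff[degen]))
  data.frame(gene = rownames(x), log2fc = unname(diff), pvalue = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, clipped to 1 and order-preserving on the input
#' ordering. Input p-values must lie in (0, 1].
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("p-values must be numeric", call. = FALSE)
  if (any(is.na(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

direction_call <- function(log2fc, padj, alpha, min_abs_lfc) {
  ifelse(padj < alpha & log2fc > min_abs_lfc, "up",
         ifelse(padj < alpha & log2fc < -min_abs_lfc, "down", "none"))
}

#' Per-study differential-expression table
#'
#' Runs the full single-study stage on a count matrix: log2-CPM, Welch's t per
#' gene, BH adjustment, and the direction call (`up` / `down` / `none`) at the
#' given thresholds.
#'
#' @param em An [expression_matrix()] of counts.
#' @param alpha Adjusted-p threshold for significance.
#' @param min_abs_lfc Minimum |log2FC| for a direction call.
#' @param pseudocount Passed to [log_cpm()].
#' @param study_id Identifier stored with the result.
#' @return A `study_de_result`: data frame `gene`, `log2fc`, `pvalue`, `padj`,
#'   `direction`, with the thresholds and study id kept as attributes.
#' @export
run_de <- function(em, alpha = 0.05, min_abs_lfc = 0, pseudocount = 1,
                   study_id = "study") {
  res <- welch_test(log_cpm(em, pseudocount))
  res$padj <- bh_adjust(res$pvalue)
  res$direction <- direction_call(res$log2fc, res$padj, alpha, min_abs_lfc)
  structure(res, class = c("study_de_result", "data.frame"),
            alpha = alpha, min_abs_lfc = min_abs_lfc, study_id = study_id)
}

#' Call differentially expressed genes from a DE table
#'
#' A gene is `up` iff `padj < alpha` and `log2fc > min_abs_lfc`, `down` iff
#' `padj < alpha` and `log2fc < -min_abs_lfc`; the universe is all tested
#' genes.
#'
#' @param result A `study_de_result` (or data frame with `gene`, `log2fc`,
#'   `padj`).
#' @param alpha,min_abs_lfc Calling thresholds (both must be >= 0).
#' @return A `deg_set`: list with `study_id`, `up`, `down`, `universe`.
#' @export
call_degs <- function(result, alpha = 0.05, min_abs_lfc = 0) {
  if (alpha < 0 || min_abs_lfc < 0)
    stop("thresholds must be non-negative", call. = FALSE)
  dir <- direction_call(result$log2fc, result$padj, alpha, min_abs_lfc)
  structure(list(study_id = attr(result, "study_id") %||% "study",
                 up = result$gene[dir == "up"],
                 down = result$gene[dir == "down"],
                 universe = result$gene),
            class = "deg_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ingest an externally computed differential-expression table
#'
#' Reads a TSV (or takes a data frame) with columns `gene`, `log2fc`,
#' `pvalue` and optionally `padj`; a missing `padj` column is filled by
#' [bh_adjust()]. Duplicate genes and missing required columns are rejected
#' with the offender named. This allows per-study tables produced by external
#' tools (e.g. DESeq2 or limma) to enter the pipeline unchanged.
#'
#' @param x Path to a tab-separated file with a header row, or a data frame.
#' @param alpha,min_abs_lfc Thresholds used for the stored direction call.
#' @param study_id Identifier stored with the result.
#' @return A `study_de_result` (see [run_de()]).
#' @export
ingest_de_table <- function(x, alpha = 0.05, min_abs_lfc = 0,
                            study_id = "study") {
  if (is.character(x))
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  required <- c("gene", "log2fc", "pvalue")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop(sprintf("DE table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  dup <- unique(x$gene[duplicated(x$gene)])
  if (length(dup))
    stop(sprintf("duplicate gene(s) in DE table: %s",
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  if (any(is.na(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (!"padj" %in% names(x)) x$padj <- bh_adjust(x$pvalue)
  res <- data.frame(gene = as.character(x$gene), log2fc = x$log2fc,
                    pvalue = x$pvalue, padj = x$padj,
                    stringsAsFactors = FALSE)
  res$direction <- direction_call(res$log2fc, res$padj, alpha, min_abs_lfc)
  structure(res, class = c("study_de_result", "data.frame"),
            alpha = alpha, min_abs_lfc = min_abs_lfc, study_id = study_id)
}
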