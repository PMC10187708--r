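#' Two-group expression matrix
#'
#' Lightweight container for a genes-by-samples expression matrix with a
#' per-sample case/control group label, the unit of input for a single
#' differential-expression contrast (e.g. old vs young participants of one
#' study, or model vs control animals).
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty dimnames. Counts must be non-negative.
#' @param group Character or factor of length `ncol(values)` with levels
#'   `"case"` and `"control"`; `"case"` is the numerator of every fold change.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `group` (a factor with levels case/control).
#' @export
#' @examples
#' m <- matrix(rpois(20, 10), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' em <- expression_matrix(m, c("case", "case", "control", "control"))
expression_matrix <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene (row) and sample (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in 'values'", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in 'values'", call. = FALSE)
  if (any(values < 0)) stop("negative expression values", call. = FALSE)
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("one group label per sample is required", call. = FALSE)
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  if (!all(c("case", "control") %in% group))
    stop("both groups must be non-empty", call. = FALSE)
  structure(list(values = values,
                 group = factor(group, levels = c("case", "control"))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)
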