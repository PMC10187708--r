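#' Gene set collection
#'
#' @param sets Named list of character vectors of gene ids; names unique,
#'   sets non-empty.
#' @param description Optional per-set description (recycled if length 1).
#' @return Object of class `gene_set_collection` (a named list with a
#'   `description` attribute).
#' @export
gene_set_collection <- function(sets, description = "") {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("'sets' must be a fully named list", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("gene set names must be unique", call. = FALSE)
  if (any(lengths(sets) == 0L))
    stop("gene sets must be non-empty", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  description <- rep_len(as.character(description), length(sets))
  structure(sets, class = "gene_set_collection",
            description = stats::setNames(description, names(sets)))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' Standard tab-separated GMT: set name, description, then members. A missing
#' description field is tolerated on read (the line must still have at least
#' one member).
#'
#' @param path File path.
#' @return `read_gmt` returns a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(sprintf("malformed GMT line(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  nm <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, function(p)
    if (length(p) >= 3L) p[[2L]] else "", character(1))
  members <- lapply(parts, function(p)
    if (length(p) >= 3L) p[-(1:2)] else p[-1L])
  gene_set_collection(stats::setNames(members, nm), desc)
}

#' @rdname read_gmt
#' @param collection A [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "description") %||% rep("", length(collection))
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], desc[[i]], collection[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` marked elements when `n` elements are drawn without
#' replacement from a universe of `N` containing `K` marked ones. This is the
#' over-representation p-value of an overlap of size `k` between a query of
#' size `n` and a gene set of size `K`.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Gene-set size within the universe.
#' @param n Query size.
#' @param N Universe size (K <= N, n <= N).
#' @return The upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & N >= 0 & K <= N & n <= N & k <= pmin(K, n)
  if (any(!ok))
    stop("inconsistent hypergeometric arguments (need 0 <= k <= min(K, n), K <= N, n <= N)",
         call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a query gene list
#'
#' For every set in the collection, intersects the set with the tested
#' universe (giving `K`), counts the overlap `k` with the query, and computes
#' the one-sided hypergeometric upper-tail p-value. Sets with `K = 0` are
#' reported with p-value 1. No multiple-testing correction is applied across
#' sets: a set is a differentially expressed pathway (DEP) when its raw
#' p-value falls below `dep_alpha` (default 0.01).
#'
#' @param query_genes Character vector; must be a subset of `universe`.
#' @param universe Character vector of all tested genes.
#' @param collection A [gene_set_collection()].
#' @param dep_alpha Raw-p threshold defining a DEP.
#' @return An `enrichment_result`: data frame with columns `set`, `k`, `K`,
#'   `n`, `N`, `pvalue`, `is_dep`; `dep_alpha` kept as attribute.
#' @export
enrich <- function(query_genes, universe, collection, dep_alpha = 0.01) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query_genes <- unique(as.character(query_genes))
  universe <- unique(as.character(universe))
  outside <- setdiff(query_genes, universe)
  if (length(outside))
    stop(sprintf("query gene(s) outside the universe: %s%s",
                 paste(utils::head(outside, 5), collapse = ", "),
                 if (length(outside) > 5) sprintf(" (and %d more)",
                                                  length(outside) - 5) else ""),
         call. = FALSE)
  N <- length(universe)
  n <- length(query_genes)
  K <- vapply(collection, function(s) length(intersect(s, universe)),
              integer(1))
  k <- vapply(collection, function(s) length(intersect(s, query_genes)),
              integer(1))
  p <- rep(1, length(collection))
  nz <- K > 0L
  p[nz] <- hypergeom_upper_tail(k[nz], K[nz], n, N)
  structure(data.frame(set = names(collection), k = unname(k), K = unname(K),
                       n = n, N = N, pvalue = unname(p),
                       is_dep = unname(p) < dep_alpha,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"),
            dep_alpha = dep_alpha)
}

#' Ordered table of differentially expressed pathways
#'
#' DEPs (sets with `is_dep`) sorted by ascending p-value, ties broken
#' lexicographically by set name.
#'
#' @param result An `enrichment_result` from [enrich()].
#' @return The DEP rows of `result`, reordered.
#' @export
dep_list <- function(result) {
  deps <- result[result$is_dep, , drop = FALSE]
  deps <- deps[order(deps$pvalue, deps$set), , drop = FALSE]
  rownames(deps) <- NULL
  deps
}
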