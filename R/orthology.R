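#' Read an ortholog table
#'
#' Tab-separated with header `source_id`, `target_id` and optional
#' `confidence`. Duplicate (source, target) pairs are rejected.
#'
#' @param path File path.
#' @return Data frame with the validated columns.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input file not found: '%s'", path), call. = FALSE)
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ortholog_map(map)
}

validate_ortholog_map <- function(map) {
  if (!all(c("source_id", "target_id") %in% names(map)))
    stop("ortholog map needs columns 'source_id' and 'target_id'",
         call. = FALSE)
  if (anyDuplicated(map[, c("source_id", "target_id")]))
    stop("duplicate (source_id, target_id) pairs in ortholog map",
         call. = FALSE)
  map
}

filter_map_by_policy <- function(map, policy) {
  switch(policy,
    one_to_one_only = {
      src_n <- table(map$source_id)
      tgt_n <- table(map$target_id)
      map[src_n[map$source_id] == 1L & tgt_n[map$target_id] == 1L, ,
          drop = FALSE]
    },
    best_confidence = {
      if (!"confidence" %in% names(map) || any(is.na(map$confidence)))
        stop("policy 'best_confidence' requires a complete 'confidence' column",
             call. = FALSE)
      # highest confidence per source; ties -> lexicographically smallest target
      map <- map[order(map$source_id, -map$confidence, map$target_id), ,
                 drop = FALSE]
      map[!duplicated(map$source_id), , drop = FALSE]
    },
    expand_all = map)
}

#' Map gene identifiers across species through an ortholog table
#'
#' Policies: `one_to_one_only` keeps only rows whose source maps to exactly
#' one target and whose target is reached from exactly one source (a
#' bijection, the default, preventing double counting in vote tallies and
#' enrichment); `best_confidence` keeps the highest-confidence target per
#' source (ties broken by the lexicographically smallest target);
#' `expand_all` keeps every pair. Inputs with no surviving mapping are listed
#' in the `unmapped` element.
#'
#' @param x Character vector of gene ids, or a DE-style data frame with a
#'   `gene` column (e.g. a `study_de_result`).
#' @param map Ortholog data frame (`source_id`, `target_id`, optional
#'   `confidence`).
#' @param policy One of `"one_to_one_only"`, `"best_confidence"`,
#'   `"expand_all"`.
#' @return List with `result` (mapped vector, or the data frame with `gene`
#'   rewritten to the target namespace; under `expand_all`, duplicate targets
#'   arising in a table are collapsed to the smallest-p row) and `unmapped`
#'   (source ids dropped).
#' @export
map_genes <- function(x, map,
                      policy = c("one_to_one_only", "best_confidence",
                                 "expand_all")) {
  policy <- match.arg(policy)
  map <- validate_ortholog_map(map)
  fmap <- filter_map_by_policy(map, policy)
  if (is.data.frame(x)) {
    if (!"gene" %in% names(x))
      stop("data-frame input must have a 'gene' column", call. = FALSE)
    idx <- match(fmap$source_id, x$gene)
    hit <- !is.na(idx)
    out <- x[idx[hit], , drop = FALSE]
    out$gene <- fmap$target_id[hit]
    if (anyDuplicated(out$gene)) {
      ord <- if ("pvalue" %in% names(out)) order(out$gene, out$pvalue)
             else order(out$gene)
      out <- out[ord, , drop = FALSE]
      out <- out[!duplicated(out$gene), , drop = FALSE]
    }
    out <- out[order(out$gene), , drop = FALSE]
    rownames(out) <- NULL
    for (a in c("alpha", "min_abs_lfc", "study_id"))
      attr(out, a) <- attr(x, a)
    unmapped <- sort(setdiff(x$gene, fmap$source_id))
    list(result = out, unmapped = unmapped)
  } else {
    x <- as.character(x)
    keep <- fmap[fmap$source_id %in% x, , drop = FALSE]
    list(result = sort(unique(keep$target_id)),
         unmapped = sort(setdiff(x, fmap$source_id)))
  }
}
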