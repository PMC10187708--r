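#' Recapitulation of a human DEP (or DEG) set by model contrasts
#'
#' For each model, the recapitulated set is the intersection of the human set
#' with that model's set, and `percent_recapitulated` is 100 times its size
#' over the human set size. Each recapitulated element is further partitioned
#' by how many of the *other* supplied models also recapitulate it: by none
#' (`unique_to_model`), by some but not all (`shared_with_some`), or by all
#' (`shared_with_all`). With a single model everything recapitulated is
#' unique to it. The same operation applies unchanged to pathway names or
#' gene ids.
#'
#' @param human_deps Non-empty character vector (the human signature, set to
#'   100%).
#' @param model_deps Named list of character vectors, one per model.
#' @return A `recapitulation_table`: data frame with one row per model and
#'   columns `model`, `n_human_deps`, `n_recapitulated`,
#'   `percent_recapitulated`, `unique_to_model`, `shared_with_some`,
#'   `shared_with_all`; the per-model recapitulated sets are kept in the
#'   `recapitulated` attribute.
#' @export
recapitulation <- function(human_deps, model_deps) {
  human_deps <- unique(as.character(human_deps))
  if (length(human_deps) == 0L)
    stop("'human_deps' is empty: percentages are undefined", call. = FALSE)
  if (!is.list(model_deps) || length(model_deps) < 1L ||
      is.null(names(model_deps)) || any(names(model_deps) == ""))
    stop("'model_deps' must be a named list with at least one model",
         call. = FALSE)
  recap <- lapply(model_deps, function(s) intersect(human_deps, unique(s)))
  n_models <- length(model_deps)
  rows <- lapply(names(model_deps), function(m) {
    r <- recap[[m]]
    others <- vapply(r, function(p)
      sum(vapply(recap[setdiff(names(recap), m)],
                 function(s) p %in% s, logical(1))), integer(1))
    if (length(r) == 0L) others <- integer(0)
    data.frame(model = m, n_human_deps = length(human_deps),
               n_recapitulated = length(r),
               percent_recapitulated = 100 * length(r) / length(human_deps),
               unique_to_model = sum(others == 0L),
               shared_with_some = sum(others > 0L & others < n_models - 1L),
               shared_with_all = if (n_models == 1L) 0L
                                 else sum(others == n_models - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # single-model case: everything it recapitulates is unique to it
  if (n_models == 1L) out$unique_to_model <- out$n_recapitulated
  rownames(out) <- NULL
  structure(out, class = c("recapitulation_table", "data.frame"),
            recapitulated = recap)
}

#' Exact Venn region counts for two or three named sets
#'
#' @param named_sets Named list of 2 or 3 character vectors.
#' @return Named integer vector over all 2^m - 1 membership patterns; region
#'   names join the member set names with `&` (e.g. `"A&B"` is the
#'   elements in exactly A and B). Counts sum to the size of the union.
#' @export
venn_counts <- function(named_sets) {
  m <- length(named_sets)
  if (!is.list(named_sets) || m < 2L || m > 3L)
    stop("venn_counts supports exactly 2 or 3 named sets", call. = FALSE)
  if (is.null(names(named_sets)) || any(names(named_sets) == ""))
    stop("sets must be named", call. = FALSE)
  named_sets <- lapply(named_sets, unique)
  elements <- unique(unlist(named_sets, use.names = FALSE))
  membership <- vapply(named_sets, function(s) elements %in% s,
                       logical(length(elements)))
  if (length(elements) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1L, , drop = FALSE]
  counts <- apply(patterns, 1L, function(p)
    if (length(elements) == 0L) 0L
    else sum(apply(membership, 1L, function(row) all(row == p))))
  names(counts) <- apply(patterns, 1L, function(p)
    paste(names(named_sets)[as.logical(p)], collapse = "&"))
  counts[order(names(counts))]
}

#' Top-N human pathways and their differential expression in each model
#'
#' Ranks the human DEPs by ascending enrichment p-value (ties broken by set
#' name), keeps the top `n`, and reports each model's -log10 p-value for the
#' same pathways together with a recapitulated flag (the model's `is_dep`
#' call). A pathway missing from a model's result is reported with -log10 p
#' of 0 and flagged absent.
#'
#' @param human_enrichment An `enrichment_result` for the human signature.
#' @param model_enrichments Named list of `enrichment_result`s, one per
#'   model.
#' @param n Number of top pathways (default 10).
#' @return Data frame with `pathway`, `human_mlog10p`, then per model
#'   `<model>_mlog10p`, `<model>_recapitulated`, `<model>_absent`; the named
#'   vector of per-model counts of recapitulated top-n pathways is kept in
#'   the `n_recapitulated` attribute.
#' @export
top_n_table <- function(human_enrichment, model_enrichments, n = 10) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  top <- utils::head(dep_list(human_enrichment), n)
  out <- data.frame(pathway = top$set,
                    human_mlog10p = -log10(top$pvalue),
                    stringsAsFactors = FALSE)
  counts <- integer(length(model_enrichments))
  names(counts) <- names(model_enrichments)
  for (m in names(model_enrichments)) {
    res <- model_enrichments[[m]]
    idx <- match(top$set, res$set)
    absent <- is.na(idx)
    mlog <- ifelse(absent, 0, -log10(res$pvalue[idx]))
    recap <- !absent & res$is_dep[idx]
    out[[paste0(m, "_mlog10p")]] <- mlog
    out[[paste0(m, "_recapitulated")]] <- recap
    out[[paste0(m, "_absent")]] <- absent
    counts[[m]] <- sum(recap)
  }
  structure(out, n_recapitulated = counts)
}

#' Biological-category rollup of DEG recapitulation
#'
#' Assigns every human DEP to a biological category (pathways without an
#' assignment fall into `"uncategorized"`), takes as each category's human
#' DEG set the union of retained consensus genes belonging to any of its
#' DEPs' member sets, and, per model, counts how many of those DEGs are also
#' differentially expressed in the model and what percentage of the
#' recapitulated DEGs keep the human direction (sign of the model log2FC
#' versus sign of the consensus `summary_lfc`; pairs with a zero on either
#' side are excluded from the percentage).
#'
#' @param consensus A `consensus_signature`.
#' @param model_results Named list of `study_de_result`s in the human gene
#'   namespace (ortholog-mapped).
#' @param categories Named character vector or two-column data frame
#'   (`pathway`, `category`) assigning DEPs to categories.
#' @param collection The [gene_set_collection()] defining DEP membership.
#' @param human_deps Character vector of human DEP names.
#' @return Data frame with columns `category`, `model`, `n_human_degs`,
#'   `n_recapitulated`, `percent_same_direction`.
#' @export
category_rollup <- function(consensus, model_results, categories, collection,
                            human_deps) {
  if (is.data.frame(categories))
    categories <- stats::setNames(as.character(categories$category),
                                  categories$pathway)
  human_deps <- unique(as.character(human_deps))
  cat_of <- categories[human_deps]
  cat_of[is.na(cat_of)] <- "uncategorized"
  retained <- consensus_genes(consensus)
  hlfc <- stats::setNames(consensus$summary_lfc, consensus$gene)
  rows <- list()
  for (cg in sort(unique(cat_of))) {
    deps_c <- human_deps[cat_of == cg]
    genes_c <- sort(intersect(
      unique(unlist(collection[intersect(deps_c, names(collection))],
                    use.names = FALSE)),
      retained))
    for (m in names(model_results)) {
      res <- model_results[[m]]
      idx <- match(genes_c, res$gene)
      sig <- !is.na(idx) & res$direction[idx] != "none"
      recap <- genes_c[sig]
      if (length(recap)) {
        prod_sign <- sign(hlfc[recap]) * sign(res$log2fc[match(recap,
                                                               res$gene)])
        nz <- prod_sign != 0
        pct <- if (any(nz)) 100 * mean(prod_sign[nz] > 0) else NA_real_
      } else pct <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        category = cg, model = m, n_human_degs = length(genes_c),
        n_recapitulated = length(recap), percent_same_direction = pct,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-level direction-of-regulation concordance
#'
#' Pairs the consensus human effect (`summary_lfc`) with the model log2 fold
#' change over the genes in scope and classifies each pair by the sign of the
#' product: concordant (same direction, the second/third quadrants of the
#' human-vs-model fold-change plot) or discordant. Pairs with an exact zero
#' on either axis lie on an axis, are excluded, and are counted in
#' `n_zero_excluded`.
#'
#' @param consensus A `consensus_signature` (with non-`NA` `summary_lfc`).
#' @param model_result A `study_de_result` in the human namespace.
#' @param gene_scope `"shared_degs"` (default: genes retained in the
#'   consensus *and* called in the model) or `"all_consensus"` (all retained
#'   consensus genes present in the model's universe).
#' @return A list of class `quadrant_concordance`: `pairs` (data frame
#'   `gene`, `human_lfc`, `model_lfc`), `percent_concordant`,
#'   `percent_discordant`, `n_pairs`, `n_zero_excluded`.
#' @export
direction_concordance <- function(consensus, model_result,
                                  gene_scope = c("shared_degs",
                                                 "all_consensus")) {
  gene_scope <- match.arg(gene_scope)
  retained <- consensus_genes(consensus)
  idx <- match(retained, model_result$gene)
  present <- !is.na(idx)
  in_scope <- if (gene_scope == "shared_degs")
    present & model_result$direction[idx] != "none" else present
  genes <- retained[in_scope]
  if (length(genes) == 0L)
    stop("no genes in scope after intersecting consensus and model",
         call. = FALSE)
  human_lfc <- consensus$summary_lfc[match(genes, consensus$gene)]
  model_lfc <- model_result$log2fc[match(genes, model_result$gene)]
  prod_sign <- sign(human_lfc) * sign(model_lfc)
  nz <- prod_sign != 0 & !is.na(prod_sign)
  if (!any(nz))
    stop("all in-scope pairs have a zero fold change on one axis",
         call. = FALSE)
  structure(list(
    pairs = data.frame(gene = genes, human_lfc = human_lfc,
                       model_lfc = model_lfc, stringsAsFactors = FALSE),
    percent_concordant = 100 * mean(prod_sign[nz] > 0),
    percent_discordant = 100 * mean(prod_sign[nz] < 0),
    n_pairs = sum(nz), n_zero_excluded = sum(!nz)),
    class = "quadrant_concordance")
}

#' @export
print.quadrant_concordance <- function(x, ...) {
  cat(sprintf("quadrant_concordance: %d pairs, %.1f%% concordant, %.1f%% discordant (%d zero pairs excluded)\n",
              x$n_pairs, x$percent_concordant, x$percent_discordant,
              x$n_zero_excluded))
  invisible(x)
}
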