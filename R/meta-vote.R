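#' Vote-counting consensus across study DEG sets
#'
#' A gene enters the consensus signature with direction `d` when at least
#' `min_support` studies call it differentially expressed in direction `d`
#' and fewer than `min_support` call the opposite direction. Genes for which
#' both directions independently reach the support threshold are flagged
#' `conflicted`, excluded from the retained signature, but reported. A gene
#' absent from a study's tested universe counts as "no call" in that study.
#'
#' When the per-study DE tables are supplied, the consensus effect size
#' (`summary_lfc`) is the median log2 fold change across the studies
#' supporting the retained direction; otherwise it is `NA`.
#'
#' @param deg_sets List of `deg_set` objects (see [call_degs()]).
#' @param min_support Minimum number of same-direction studies (default 2).
#' @param de_results Optional list of `study_de_result` tables, parallel to
#'   `deg_sets`, used for `summary_lfc`.
#' @param universe_policy `"intersection"` (default) or `"union"` of the
#'   per-study tested universes; kept as the `universe` attribute and used as
#'   the enrichment background downstream.
#' @return A `consensus_signature`: data frame with columns `gene`,
#'   `direction` (`NA` for conflicted genes), `support`, `summary_lfc`,
#'   `conflicted`, sorted by gene; attributes `universe` and `min_support`.
#' @export
consensus_degs <- function(deg_sets, min_support = 2, de_results = NULL,
                           universe_policy = c("intersection", "union")) {
  universe_policy <- match.arg(universe_policy)
  min_support <- as.integer(min_support)
  if (is.na(min_support) || min_support < 1L)
    stop("'min_support' must be a count >= 1", call. = FALSE)
  if (length(deg_sets) < min_support)
    stop("fewer studies supplied than 'min_support'", call. = FALSE)
  if (any(vapply(deg_sets, function(d) length(d$universe) == 0L, logical(1))))
    stop("every study must have a non-empty universe", call. = FALSE)

  up_tab <- table(unlist(lapply(deg_sets, `[[`, "up")))
  down_tab <- table(unlist(lapply(deg_sets, `[[`, "down")))
  genes <- sort(union(names(up_tab), names(down_tab)))
  up_n <- as.integer(up_tab[genes]); up_n[is.na(up_n)] <- 0L
  down_n <- as.integer(down_tab[genes]); down_n[is.na(down_n)] <- 0L

  keep <- up_n >= min_support | down_n >= min_support
  genes <- genes[keep]; up_n <- up_n[keep]; down_n <- down_n[keep]
  conflicted <- up_n >= min_support & down_n >= min_support
  direction <- ifelse(conflicted, NA_character_,
                      ifelse(up_n >= min_support, "up", "down"))
  support <- pmax(up_n, down_n)

  summary_lfc <- rep(NA_real_, length(genes))
  if (!is.null(de_results) && length(genes)) {
    lfc_of <- lapply(de_results, function(r)
      stats::setNames(r$log2fc, r$gene))
    supp_sets <- lapply(deg_sets, function(d)
      list(up = d$up, down = d$down))
    for (j in seq_along(genes)) {
      if (conflicted[j]) next
      g <- genes[j]
      vals <- unlist(lapply(seq_along(deg_sets), function(i) {
        called <- g %in% supp_sets[[i]][[direction[j]]]
        if (called) lfc_of[[i]][[g]] else NULL
      }))
      summary_lfc[j] <- stats::median(vals)
    }
  }

  universes <- lapply(deg_sets, `[[`, "universe")
  universe <- if (universe_policy == "intersection")
    Reduce(intersect, universes) else Reduce(union, universes)

  structure(data.frame(gene = genes, direction = direction,
                       support = support, summary_lfc = summary_lfc,
                       conflicted = conflicted, stringsAsFactors = FALSE),
            class = c("consensus_signature", "data.frame"),
            universe = sort(universe), min_support = min_support)
}

#' Retained genes of a consensus signature
#'
#' @param cs A `consensus_signature`.
#' @param direction Optionally restrict to `"up"` or `"down"` genes.
#' @return Character vector of retained (non-conflicted) consensus genes.
#' @export
consensus_genes <- function(cs, direction = NULL) {
  keep <- !cs$conflicted
  if (!is.null(direction)) keep <- keep & cs$direction %in% direction
  cs$gene[keep]
}
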