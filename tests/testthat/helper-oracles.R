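# Independent brute-force oracles; deliberately naive so they cannot share a
# defect with the implementation they check.

# BH step-up applied literally: sort, p*(m/i), cumulative min from the top,
# clip at 1, restore input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# P(X >= k) by explicit summation over the hypergeometric support.
hyper_tail_oracle <- function(k, K, n, N) {
  js <- seq(k, min(K, n))
  if (length(js) == 0L) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Per-gene tally of up/down calls over a list of deg_set-like lists.
consensus_tally_oracle <- function(deg_sets, min_support) {
  genes <- sort(unique(unlist(lapply(deg_sets, function(d) c(d$up, d$down)))))
  rows <- lapply(genes, function(g) {
    up <- sum(vapply(deg_sets, function(d) g %in% d$up, logical(1)))
    down <- sum(vapply(deg_sets, function(d) g %in% d$down, logical(1)))
    if (up < min_support && down < min_support) return(NULL)
    conflicted <- up >= min_support && down >= min_support
    data.frame(gene = g,
               direction = if (conflicted) NA_character_
                           else if (up >= min_support) "up" else "down",
               support = max(up, down), conflicted = conflicted,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# Per-element membership-pattern tally over named sets.
venn_oracle <- function(sets) {
  elements <- unique(unlist(sets))
  m <- length(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1L, , drop = FALSE]
  counts <- apply(patterns, 1L, function(p) {
    sum(vapply(elements, function(e) {
      inside <- vapply(sets, function(s) e %in% s, logical(1))
      all(inside == as.logical(p))
    }, logical(1)))
  })
  names(counts) <- apply(patterns, 1L, function(p)
    paste(names(sets)[as.logical(p)], collapse = "&"))
  counts[order(names(counts))]
}

random_deg_sets <- function(n_studies, n_genes, p_call = 0.2) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  lapply(seq_len(n_studies), function(i) {
    status <- sample(c("up", "down", "none"), n_genes, replace = TRUE,
                     prob = c(p_call / 2, p_call / 2, 1 - p_call))
    list(study_id = paste0("s", i), up = genes[status == "up"],
         down = genes[status == "down"], universe = genes)
  })
}
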