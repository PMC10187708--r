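test_that("recapitulation percentages on forced cases", {
  rt <- recapitulation(c("P1", "P2"), list(m = c("P1", "P2")))
  expect_equal(rt$percent_recapitulated, 100)
  expect_equal(rt$unique_to_model, 2)
  rt2 <- recapitulation(sprintf("P%d", 1:4),
                        list(m = c("P1", "P2", "P9")))
  expect_equal(rt2$n_recapitulated, 2)
  expect_equal(rt2$percent_recapitulated, 50)
  expect_error(recapitulation(character(), list(m = "P1")), "empty")
})

test_that("recapitulation equals a set-intersection oracle with exact partitions", {
  set.seed(23)
  for (rep in 1:10) {
    pool <- sprintf("P%02d", 1:12)
    human <- sample(pool, 8)
    models <- lapply(1:3, function(i) sample(pool, sample(3:10, 1)))
    names(models) <- c("a", "b", "c")
    rt <- recapitulation(human, models)
    for (m in names(models)) {
      r_oracle <- intersect(human, models[[m]])
      row <- rt[rt$model == m, ]
      expect_equal(row$n_recapitulated, length(r_oracle))
      expect_equal(row$percent_recapitulated,
                   100 * length(r_oracle) / length(human))
      # partition: classify each recapitulated pathway by the other models
      others <- setdiff(names(models), m)
      n_others <- sapply(r_oracle, function(p)
        sum(sapply(others, function(o)
          p %in% intersect(human, models[[o]]))))
      if (length(r_oracle) == 0) n_others <- integer(0)
      expect_equal(row$unique_to_model, sum(n_others == 0))
      expect_equal(row$shared_with_some, sum(n_others == 1))
      expect_equal(row$shared_with_all, sum(n_others == 2))
      expect_equal(row$unique_to_model + row$shared_with_some +
                     row$shared_with_all, row$n_recapitulated)
    }
    # model ordering does not matter
    perm <- recapitulation(human, models[c("c", "a", "b")])
    expect_equal(as.data.frame(perm[order(perm$model), ]),
                 as.data.frame(rt[order(rt$model), ]),
                 ignore_attr = TRUE)
  }
})

test_that("venn_counts matches a membership-pattern tally", {
  v <- venn_counts(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(v[["A"]], 1); expect_equal(v[["B"]], 1)
  expect_equal(v[["A&B"]], 1)
  same <- venn_counts(list(x = letters[1:5], y = letters[1:5],
                           z = letters[1:5]))
  expect_equal(same[["x&y&z"]], 5)
  expect_true(all(same[names(same) != "x&y&z"] == 0))
  set.seed(41)
  for (rep in 1:10) {
    sets <- lapply(1:3, function(i) sample(letters[1:15], sample(0:12, 1)))
    names(sets) <- c("s1", "s2", "s3")
    v <- venn_counts(sets)
    expect_equal(v, venn_oracle(sets))
    expect_equal(sum(v), length(unique(unlist(sets))))
  }
  expect_error(venn_counts(list(a = "x")), "2 or 3")
  expect_error(venn_counts(list(a = "x", b = "y", c = "z", d = "w")),
               "2 or 3")
})

enr_of <- function(sets, pvals, dep_alpha = 0.01) {
  structure(data.frame(set = sets, k = 1, K = 2, n = 3, N = 10,
                       pvalue = pvals, is_dep = pvals < dep_alpha,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"),
            dep_alpha = dep_alpha)
}

test_that("top_n_table ranks by human p with ties by name and counts recapitulation", {
  set.seed(3)
  sets <- sprintf("P%02d", 1:12)
  hp <- c(0.0001, 0.0001, round(runif(10, 1e-4, 0.009), 6))
  human <- enr_of(sets, hp)
  model_same <- human
  model_none <- enr_of(sets, rep(0.5, 12))
  tab <- top_n_table(human, list(same = model_same, none = model_none),
                     n = 10)
  ord_oracle <- sets[order(hp, sets)][1:10]
  expect_identical(tab$pathway, ord_oracle)
  expect_equal(tab$human_mlog10p, -log10(sort(hp)[1:10]))
  expect_equal(unname(attr(tab, "n_recapitulated")["same"]), 10)
  expect_equal(unname(attr(tab, "n_recapitulated")["none"]), 0)
  expect_false(any(tab$none_recapitulated))
  # a pathway missing from a model is flagged absent with -log10 p of 0
  model_missing <- enr_of(sets[-1], rep(0.001, 11))
  tab2 <- top_n_table(human, list(m = model_missing), n = 3)
  miss <- tab2$pathway == sets[1]
  expect_true(any(miss) && all(tab2$m_absent[miss]))
  expect_equal(tab2$m_mlog10p[miss], 0)
})

test_that("direction concordance counts sign-product quadrants", {
  cs <- structure(data.frame(
    gene = sprintf("g%d", 1:4), direction = c("up", "up", "up", "down"),
    support = 2L, summary_lfc = c(1, 2, 0.5, -1), conflicted = FALSE,
    stringsAsFactors = FALSE),
    class = c("consensus_signature", "data.frame"))
  model <- data.frame(gene = sprintf("g%d", 1:4),
                      log2fc = c(0.5, 1, -2, -0.3),
                      pvalue = 0.001, padj = 0.001,
                      direction = c("up", "up", "down", "down"))
  qc <- direction_concordance(cs, model)
  # signs: (+,+), (+,+), (+,-), (-,-) -> 75% concordant
  expect_equal(qc$percent_concordant, 75)
  expect_equal(qc$percent_discordant, 25)
  expect_equal(qc$n_zero_excluded, 0)
  # identical fold changes -> 100% concordant
  model2 <- model
  model2$log2fc <- cs$summary_lfc
  model2$direction <- c("up", "up", "up", "down")
  expect_equal(direction_concordance(cs, model2)$percent_concordant, 100)
  # zero on one axis is excluded and counted
  model3 <- model
  model3$log2fc[1] <- 0
  qc3 <- direction_concordance(cs, model3)
  expect_equal(qc3$n_zero_excluded, 1)
  expect_equal(qc3$n_pairs, 3)
  # scope all_consensus keeps genes the model did not call
  model4 <- model
  model4$direction <- c("up", "none", "none", "none")
  expect_equal(direction_concordance(cs, model4)$n_pairs, 1)
  expect_equal(direction_concordance(cs, model4,
                                     "all_consensus")$n_pairs, 4)
  model5 <- model
  model5$direction <- rep("none", 4)
  expect_error(direction_concordance(cs, model5), "scope")
})

test_that("concordance percentage equals a brute-force sign count on random pairs", {
  set.seed(61)
  n <- 100
  hl <- rnorm(n); ml <- rnorm(n)
  cs <- structure(data.frame(
    gene = sprintf("g%03d", 1:n), direction = ifelse(hl > 0, "up", "down"),
    support = 2L, summary_lfc = hl, conflicted = FALSE,
    stringsAsFactors = FALSE),
    class = c("consensus_signature", "data.frame"))
  model <- data.frame(gene = cs$gene, log2fc = ml, pvalue = 0.001,
                      padj = 0.001, direction = ifelse(ml > 0, "up", "down"))
  qc <- direction_concordance(cs, model)
  expect_equal(qc$percent_concordant, 100 * sum(hl * ml > 0) / n)
  expect_equal(qc$percent_concordant + qc$percent_discordant, 100)
})

test_that("category rollup equals a manual per-gene tabulation on a toy case", {
  genes <- sprintf("g%d", 1:8)
  cs <- structure(data.frame(
    gene = genes, direction = rep(c("up", "down"), 4), support = 2L,
    summary_lfc = rep(c(1, -1), 4), conflicted = FALSE,
    stringsAsFactors = FALSE),
    class = c("consensus_signature", "data.frame"))
  coll <- gene_set_collection(list(P1 = genes[1:4], P2 = genes[3:6],
                                   P3 = genes[7:8]))
  categories <- c(P1 = "metabolism", P2 = "metabolism", P3 = "inflammation")
  model <- data.frame(gene = genes,
                      log2fc = c(2, -2, -1, 1, 2, -2, 1, 0.5),
                      pvalue = 0.001, padj = 0.001,
                      direction = c("up", "down", "down", "up", "up", "down",
                                    "none", "none"))
  ru <- category_rollup(cs, list(m = model), categories, coll,
                        human_deps = c("P1", "P2", "P3"))
  met <- ru[ru$category == "metabolism", ]
  # metabolism covers g1..g6, all recapitulated except none; manual tabulation:
  expect_equal(met$n_human_degs, 6)
  expect_equal(met$n_recapitulated, 6)
  # signs agree for g1 (+,+), g2 (-,-), g4? human -1 vs model +1 no,
  # g3 human +1 vs -1 no, g5 +,+ yes, g6 -,- yes -> 4/6
  expect_equal(met$percent_same_direction, 100 * 4 / 6)
  inf <- ru[ru$category == "inflammation", ]
  expect_equal(inf$n_human_degs, 2)
  expect_equal(inf$n_recapitulated, 0)
  expect_true(is.na(inf$percent_same_direction))
  # unassigned DEPs fall into "uncategorized"
  ru2 <- category_rollup(cs, list(m = model), categories[1:2], coll,
                         human_deps = c("P1", "P2", "P3"))
  expect_true("uncategorized" %in% ru2$category)
  # a model with zero significant genes recapitulates nothing
  none <- model; none$direction <- "none"
  ru3 <- category_rollup(cs, list(m = none), categories, coll,
                         human_deps = c("P1", "P2", "P3"))
  expect_true(all(ru3$n_recapitulated == 0))
})
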