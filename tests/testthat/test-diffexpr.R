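test_that("log_cpm matches the stated formula on hand-evaluable cases", {
  m <- matrix(10, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(log_cpm(m, 1)[1, 1], log2(1e6 + 1))
  # count 5 of library size 1000, pseudocount 0.5
  m2 <- matrix(c(5, 995), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(log_cpm(m2, 0.5)["g1", 1], log2(5000.5))
  # all-zero gene -> log2(pseudocount) everywhere
  m3 <- matrix(c(0, 10, 0, 20), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(log_cpm(m3, 1)["g1", ]), c(0, 0))
  expect_equal(unname(log_cpm(m3, 0.5)["g1", ]), c(log2(0.5), log2(0.5)))
})

test_that("log_cpm rejects zero library sizes naming the sample", {
  m <- matrix(c(1, 0), 1, 2, dimnames = list("g1", c("ok", "empty")))
  expect_error(log_cpm(m), "empty")
})

test_that("welch_test agrees with stats::t.test gene by gene", {
  set.seed(42)
  x <- matrix(rnorm(30 * 11, sd = 2), 30, 11,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:11)))
  group <- rep(c("case", "control"), c(5, 6))
  res <- welch_test(x, group)
  for (i in seq_len(nrow(x))) {
    tt <- t.test(x[i, group == "case"], x[i, group == "control"])
    expect_equal(res$pvalue[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$log2fc[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
})

test_that("welch_test textbook case and degenerate inputs", {
  x <- rbind(g1 = c(2, 4, 6, 1, 2, 3))
  colnames(x) <- sprintf("s%d", 1:6)
  group <- rep(c("case", "control"), each = 3)
  res <- welch_test(x, group)
  # hand computation: m1=4, m2=2, v1=4, v2=1, se2=5/3, t=2/sqrt(5/3)
  se2 <- 4 / 3 + 1 / 3
  t_hand <- 2 / sqrt(se2)
  df_hand <- se2^2 / ((4 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(res$log2fc, 2)
  expect_equal(res$pvalue, 2 * pt(t_hand, df_hand, lower.tail = FALSE))
  # identical values in both groups -> lfc 0, p 1
  y <- rbind(g1 = rep(5, 6)); colnames(y) <- colnames(x)
  resy <- welch_test(y, group)
  expect_equal(resy$log2fc, 0)
  expect_equal(resy$pvalue, 1)
  # swapping labels negates the fold change, p unchanged
  flipped <- welch_test(x, rev(group))
  expect_equal(flipped$log2fc, -res$log2fc)
  expect_equal(flipped$pvalue, res$pvalue)
  expect_error(welch_test(x, c("case", rep("control", 5))), "at least 2")
})

test_that("bh_adjust reproduces a hand step-up and is permutation-stable", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(7)
  for (i in 1:20) {
    p <- runif(50)
    expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 1e-12)
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm])[order(perm)], bh_adjust(p),
                 tolerance = 1e-12)
  }
  # adjusted values never fall below the raw p
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("call_degs applies the thresholds row by row", {
  set.seed(11)
  tab <- data.frame(gene = sprintf("g%02d", 1:10),
                    log2fc = round(rnorm(10), 2),
                    pvalue = runif(10, 1e-4, 1))
  tab$padj <- bh_adjust(tab$pvalue)
  res <- structure(tab, class = c("study_de_result", "data.frame"),
                   study_id = "toy")
  ds <- call_degs(res, alpha = 0.3, min_abs_lfc = 0.2)
  manual_up <- tab$gene[tab$padj < 0.3 & tab$log2fc > 0.2]
  manual_down <- tab$gene[tab$padj < 0.3 & tab$log2fc < -0.2]
  expect_setequal(ds$up, manual_up)
  expect_setequal(ds$down, manual_down)
  expect_identical(ds$universe, tab$gene)
  expect_length(intersect(ds$up, ds$down), 0)
  # alpha = 0 calls nothing
  none <- call_degs(res, alpha = 0)
  expect_length(c(none$up, none$down), 0)
  # single forced case
  one <- data.frame(gene = "g1", log2fc = -1.2, pvalue = 0.005, padj = 0.01)
  expect_identical(call_degs(one, 0.05, 0)$down, "g1")
  # lowering alpha never adds genes
  strict <- call_degs(res, alpha = 0.1, min_abs_lfc = 0.2)
  expect_true(all(strict$up %in% ds$up) && all(strict$down %in% ds$down))
})

test_that("ingest_de_table validates and fills padj via BH", {
  tab <- data.frame(gene = c("a", "b", "c"), log2fc = c(1, -2, 0.5),
                    pvalue = c(0.01, 0.2, 0.04))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- ingest_de_table(path)
  expect_s3_class(res, "study_de_result")
  expect_equal(nrow(res), 3)
  expect_equal(res$padj, bh_stepup_oracle(tab$pvalue), tolerance = 1e-12)
  expect_error(ingest_de_table(tab[, c("gene", "pvalue")]), "log2fc")
  expect_error(ingest_de_table(rbind(tab, tab[1, ])), "duplicate.*a")
  bad <- tab; bad$pvalue[1] <- 0
  expect_error(ingest_de_table(bad), "\\(0, 1\\]")
  # a supplied padj column is passed through untouched
  with_padj <- tab; with_padj$padj <- c(0.5, 0.6, 0.7)
  expect_equal(ingest_de_table(with_padj)$padj, c(0.5, 0.6, 0.7))
})

test_that("run_de recovers planted genes and keeps padj >= pvalue", {
  cfg <- tiny_sim_config(seed = 31, samples_per_group = 20,
                         per_study_power = 1)
  sim <- simulate_multistudy(cfg)
  res <- run_de(sim$studies[[1]], study_id = "study1")
  expect_true(all(res$padj >= res$pvalue))
  expect_true(all(res$direction %in% c("up", "down", "none")))
  sig <- res$direction != "none"
  expect_true(all(sign(res$log2fc[sig]) ==
                    ifelse(res$direction[sig] == "up", 1, -1)))
  active <- colnames(sim$truth$per_study_active)[
    sim$truth$per_study_active[1, ]]
  recovered <- mean(res$direction[match(active, res$gene)] != "none")
  expect_gte(recovered, 0.9)
})
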