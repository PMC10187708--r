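#' Simulation configuration for a multi-study case/control design
#'
#' Defines a set of independent case/control expression studies that share a
#' planted "aging" signature: a fixed set of genes with a common signed log2
#' fold change, carried by each study with probability `per_study_power`.
#' Counts are negative binomial with gene-wise log-normal baseline means, a
#' single shared dispersion, and per-sample log-normal library-size factors so
#' the normalization stage is exercised.
#'
#' The defaults emulate a five-study human muscle-aging meta-analysis design:
#' five studies of 20 cases and 20 controls each over 2000 genes, a signature
#' of 200 genes at mean |log2FC| 1, detected by any given study with
#' probability 0.8.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_studies Number of independent studies.
#' @param samples_per_group Samples in each of case and control, per study.
#' @param signature_size Number of planted signature genes.
#' @param lfc_magnitude Mean absolute log2 fold change of planted genes.
#' @param lfc_sd Spread of the planted |log2FC| draws.
#' @param per_study_power Probability that a planted gene carries its effect
#'   in a given study.
#' @param nb_mean_log_mu,nb_mean_log_sd Log-normal (natural-log scale)
#'   parameters of the baseline gene means.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`), shared across genes.
#' @param libsize_factor_sd Log-normal sd of per-sample library-size factors.
#' @param seed Integer seed; the single source of randomness, expanded into
#'   per-study substreams so adding a study never changes earlier studies.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_studies = 5, samples_per_group = 20,
                       signature_size = 200, lfc_magnitude = 1, lfc_sd = 0.3,
                       per_study_power = 0.8,
                       nb_mean_log_mu = log(200), nb_mean_log_sd = 1.5,
                       nb_dispersion = 0.1, libsize_factor_sd = 0.2,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_studies = as.integer(n_studies),
              samples_per_group = as.integer(samples_per_group),
              signature_size = as.integer(signature_size),
              lfc_magnitude = lfc_magnitude, lfc_sd = lfc_sd,
              per_study_power = per_study_power,
              nb_mean_log_mu = nb_mean_log_mu, nb_mean_log_sd = nb_mean_log_sd,
              nb_dispersion = nb_dispersion,
              libsize_factor_sd = libsize_factor_sd, seed = as.integer(seed))
  for (f in c("n_genes", "n_studies", "samples_per_group", "signature_size"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop(sprintf("invalid sim_config: '%s' must be a count >= 1", f),
           call. = FALSE)
  if (cfg$signature_size > cfg$n_genes)
    stop("invalid sim_config: 'signature_size' exceeds 'n_genes'",
         call. = FALSE)
  if (cfg$per_study_power < 0 || cfg$per_study_power > 1)
    stop("invalid sim_config: 'per_study_power' must lie in [0,1]",
         call. = FALSE)
  for (f in c("lfc_sd", "nb_mean_log_sd", "nb_dispersion", "libsize_factor_sd"))
    if (cfg[[f]] < 0)
      stop(sprintf("invalid sim_config: '%s' must be non-negative", f),
           call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Configuration for a cross-species model dataset
#'
#' @param overlap_fraction Fraction (rho) in \[0,1\] of the planted human
#'   signature that is also perturbed in the model dataset; the simulated
#'   analogue of the recapitulation percentage.
#' @param sign_agreement Probability (kappa) in \[0,1\] that an overlapping
#'   gene keeps the human direction; the analogue of the concordant-quadrant
#'   percentage.
#' @param extra_unique Number of model-only perturbed genes drawn from outside
#'   the signature.
#' @param seed Integer seed for the model-specific substream.
#'
#' @return A validated list of class `model_sim_config`.
#' @export
model_sim_config <- function(overlap_fraction, sign_agreement,
                             extra_unique = 50, seed = 1L) {
  cfg <- list(overlap_fraction = overlap_fraction,
              sign_agreement = sign_agreement,
              extra_unique = as.integer(extra_unique), seed = as.integer(seed))
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction > 1)
    stop("invalid model_sim_config: 'overlap_fraction' must lie in [0,1]",
         call. = FALSE)
  if (cfg$sign_agreement < 0 || cfg$sign_agreement > 1)
    stop("invalid model_sim_config: 'sign_agreement' must lie in [0,1]",
         call. = FALSE)
  if (is.na(cfg$extra_unique) || cfg$extra_unique < 0)
    stop("invalid model_sim_config: 'extra_unique' must be a count >= 0",
         call. = FALSE)
  structure(cfg, class = "model_sim_config")
}

# Deterministic substream seed: each (base seed, stream index) pair maps to a
# fixed 31-bit seed, so adding a study/model never shifts earlier draws.
substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 7919) %% 2147483629)
}

human_gene_universe <- function(n_genes) sprintf("g%05d", seq_len(n_genes))

#' Human gene id -> model-species gene id (deterministic prefix namespace)
#' @noRd
model_gene_id <- function(gene) paste0("m.", gene)

nb_two_group_counts <- function(mu0, lfc_by_gene, n_per_group, dispersion,
                                libsize_factor_sd, sample_prefix) {
  n_genes <- length(mu0)
  mu_case <- mu0 * 2^lfc_by_gene
  sf <- stats::rlnorm(2L * n_per_group, 0, libsize_factor_sd)
  mu <- cbind(matrix(mu_case, n_genes, n_per_group),
              matrix(mu0, n_genes, n_per_group))
  mu <- sweep(mu, 2L, sf, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_genes, 2L * n_per_group)
  colnames(counts) <- c(sprintf("%s_case_%02d", sample_prefix,
                                seq_len(n_per_group)),
                        sprintf("%s_ctrl_%02d", sample_prefix,
                                seq_len(n_per_group)))
  counts
}

#' Simulate a multi-study case/control expression dataset with ground truth
#'
#' Draws the shared signature (genes, Rademacher signs times
#' `|N(lfc_magnitude, lfc_sd)|` magnitudes) and gene-wise baseline means from
#' the global seed, then each study from its own substream: per-study
#' activation flags (Bernoulli with `per_study_power`), library-size factors,
#' and negative-binomial counts. Case-group means of genes active in a study
#' are the control means times `2^log2FC`.
#'
#' @param config A [sim_config()].
#' @return A list with `studies` (named list of [expression_matrix()], one per
#'   study) and `truth`, a `synthetic_truth` list recording the planted
#'   signature (`gene`, `sign`, `lfc`), the study-by-gene activation matrix
#'   `per_study_active`, the gene `universe`, and an initially empty
#'   `model_active` record.
#' @export
simulate_multistudy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  universe <- human_gene_universe(config$n_genes)
  set.seed(config$seed)
  sig_idx <- sort(sample.int(config$n_genes, config$signature_size))
  signs <- sample(c(-1, 1), config$signature_size, replace = TRUE)
  lfc <- signs * abs(stats::rnorm(config$signature_size,
                                  config$lfc_magnitude, config$lfc_sd))
  base_mu <- stats::rlnorm(config$n_genes, config$nb_mean_log_mu,
                           config$nb_mean_log_sd)
  study_ids <- sprintf("study%d", seq_len(config$n_studies))
  active <- matrix(FALSE, config$n_studies, config$signature_size,
                   dimnames = list(study_ids, universe[sig_idx]))
  studies <- vector("list", config$n_studies)
  names(studies) <- study_ids
  for (i in seq_len(config$n_studies)) {
    set.seed(substream_seed(config$seed, i))
    active[i, ] <- stats::runif(config$signature_size) < config$per_study_power
    lfc_by_gene <- numeric(config$n_genes)
    lfc_by_gene[sig_idx[active[i, ]]] <- lfc[active[i, ]]
    counts <- nb_two_group_counts(base_mu, lfc_by_gene,
                                  config$samples_per_group,
                                  config$nb_dispersion,
                                  config$libsize_factor_sd, study_ids[i])
    rownames(counts) <- universe
    studies[[i]] <- expression_matrix(
      counts, rep(c("case", "control"), each = config$samples_per_group))
  }
  truth <- structure(
    list(signature = data.frame(gene = universe[sig_idx], sign = signs,
                                lfc = lfc, stringsAsFactors = FALSE),
         per_study_active = active,
         universe = universe,
         base_mu = base_mu,
         model_active = list()),
    class = "synthetic_truth")
  list(studies = studies, truth = truth)
}

#' Simulate a model-species dataset overlapping the planted signature
#'
#' Builds a two-group count matrix in the model-species gene namespace (human
#' ids carry a deterministic `m.` prefix) whose perturbed gene set overlaps
#' the planted human signature in exactly `round(overlap_fraction *
#' signature_size)` genes. Each overlapping gene keeps the human sign with
#' probability `sign_agreement` (magnitude retained either way);
#' `extra_unique` additional genes outside the signature get fresh effects.
#'
#' @param config The [sim_config()] that produced `truth` (gene universe and
#'   count-model parameters are reused).
#' @param model_cfg A [model_sim_config()].
#' @param truth The `synthetic_truth` from [simulate_multistudy()].
#' @param model_id Name under which the model's truth record is stored.
#' @return A list with `matrix` (an [expression_matrix()] in the model
#'   namespace) and `truth`, the input truth with a `model_active` entry
#'   added: a data frame of perturbed genes (human-namespace `gene`,
#'   `model_gene`, `sign`, `lfc`, `in_signature`, `kept_sign`).
#' @export
simulate_model_dataset <- function(config, model_cfg, truth,
                                   model_id = "model") {
  stopifnot(inherits(config, "sim_config"),
            inherits(model_cfg, "model_sim_config"),
            inherits(truth, "synthetic_truth"))
  if (!identical(truth$universe, human_gene_universe(config$n_genes)))
    stop("gene universe mismatch between 'config' and 'truth'", call. = FALSE)
  set.seed(substream_seed(model_cfg$seed, 104729L))
  sig <- truth$signature
  n_overlap <- round(model_cfg$overlap_fraction * nrow(sig))
  overlap_idx <- sort(sample.int(nrow(sig), n_overlap))
  kept <- stats::runif(n_overlap) < model_cfg$sign_agreement
  non_sig <- setdiff(truth$universe, sig$gene)
  if (model_cfg$extra_unique > length(non_sig))
    stop("'extra_unique' exceeds the number of non-signature genes",
         call. = FALSE)
  extra <- sort(sample(non_sig, model_cfg$extra_unique))
  extra_sign <- sample(c(-1, 1), length(extra), replace = TRUE)
  extra_lfc <- extra_sign * abs(stats::rnorm(length(extra),
                                             config$lfc_magnitude,
                                             config$lfc_sd))
  perturbed <- data.frame(
    gene = c(sig$gene[overlap_idx], extra),
    sign = c(sig$sign[overlap_idx] * ifelse(kept, 1, -1), extra_sign),
    lfc = c(abs(sig$lfc[overlap_idx]) * sig$sign[overlap_idx] *
              ifelse(kept, 1, -1), extra_lfc),
    in_signature = c(rep(TRUE, n_overlap), rep(FALSE, length(extra))),
    kept_sign = c(kept, rep(NA, length(extra))),
    stringsAsFactors = FALSE)
  perturbed$model_gene <- model_gene_id(perturbed$gene)

  lfc_by_gene <- numeric(config$n_genes)
  names(lfc_by_gene) <- truth$universe
  lfc_by_gene[perturbed$gene] <- perturbed$lfc
  counts <- nb_two_group_counts(truth$base_mu, unname(lfc_by_gene),
                                config$samples_per_group,
                                config$nb_dispersion,
                                config$libsize_factor_sd, model_id)
  rownames(counts) <- model_gene_id(truth$universe)
  truth$model_active[[model_id]] <- perturbed
  list(matrix = expression_matrix(
         counts, rep(c("case", "control"), each = config$samples_per_group)),
       truth = truth)
}

#' Generate gene sets with a known enriched fraction
#'
#' Produces a GMT-writable collection in which
#' `round(enriched_fraction * n_sets)` sets draw a majority
#' (`enriched_majority`) of their members from the planted signature and the
#' remainder draw uniformly from the gene universe (null sets). Which sets are
#' enriched is recorded in the `is_enriched` attribute for recovery tests.
#'
#' @param truth A `synthetic_truth` carrying the universe and signature.
#' @param n_sets Number of gene sets.
#' @param set_size Members per set (all sets equal-sized).
#' @param enriched_fraction Fraction of sets planted as enriched.
#' @param seed Integer seed.
#' @param enriched_majority Fraction of an enriched set's members drawn from
#'   the signature.
#' @return A [gene_set_collection()] with logical attribute `is_enriched`.
#' @export
generate_genesets <- function(truth, n_sets, set_size, enriched_fraction,
                              seed = 1L, enriched_majority = 0.8) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_sets <- as.integer(n_sets)
  set_size <- as.integer(set_size)
  if (is.na(n_sets) || n_sets < 1L)
    stop("'n_sets' must be a count >= 1", call. = FALSE)
  if (is.na(set_size) || set_size < 1L)
    stop("'set_size' must be a count >= 1", call. = FALSE)
  if (set_size > length(truth$universe))
    stop("'set_size' exceeds the gene universe", call. = FALSE)
  if (enriched_fraction < 0 || enriched_fraction > 1)
    stop("'enriched_fraction' must lie in [0,1]", call. = FALSE)
  set.seed(substream_seed(seed, 15485863L))
  n_enriched <- round(enriched_fraction * n_sets)
  sig <- truth$signature$gene
  non_sig <- setdiff(truth$universe, sig)
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  is_enriched <- c(rep(TRUE, n_enriched), rep(FALSE, n_sets - n_enriched))
  for (i in seq_len(n_sets)) {
    if (is_enriched[i]) {
      n_sig <- min(ceiling(enriched_majority * set_size), length(sig))
      sets[[i]] <- c(sample(sig, n_sig),
                     sample(non_sig, set_size - n_sig))
    } else {
      sets[[i]] <- sample(truth$universe, set_size)
    }
    sets[[i]] <- sort(sets[[i]])
  }
  out <- gene_set_collection(
    sets, description = ifelse(is_enriched, "planted-enriched", "null"))
  attr(out, "is_enriched") <- stats::setNames(is_enriched, names(sets))
  out
}

#' Generate a human/model ortholog table
#'
#' One-to-one by construction (`m.<gene>` -> `<gene>`), with an optional
#' fraction of additional one-to-many rows (a source mapped to a second,
#' random target at lower confidence) to exercise the orthology policies.
#'
#' @param universe Character vector of human gene ids.
#' @param one_to_many_fraction Fraction of genes given a second target row.
#' @param seed Integer seed (only used when `one_to_many_fraction > 0`).
#' @return A data frame with columns `source_id`, `target_id`, `confidence`.
#' @export
generate_ortholog_map <- function(universe, one_to_many_fraction = 0,
                                  seed = 1L) {
  if (one_to_many_fraction < 0 || one_to_many_fraction > 1)
    stop("'one_to_many_fraction' must lie in [0,1]", call. = FALSE)
  map <- data.frame(source_id = model_gene_id(universe), target_id = universe,
                    confidence = 1, stringsAsFactors = FALSE)
  n_extra <- round(one_to_many_fraction * length(universe))
  if (n_extra > 0) {
    if (length(universe) < 2L)
      stop("one-to-many rows require at least two genes", call. = FALSE)
    set.seed(substream_seed(seed, 32452843L))
    src <- sample(universe, n_extra)
    other <- vapply(src, function(g) sample(setdiff(universe, g), 1L),
                    character(1))
    map <- rbind(map, data.frame(source_id = model_gene_id(src),
                                 target_id = unname(other), confidence = 0.5,
                                 stringsAsFactors = FALSE))
  }
  rownames(map) <- NULL
  map
}
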