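#' Pipeline configuration
#'
#' Bundles the thresholds and policies of the full analysis. Thresholds are
#' validated once here so stage functions can assume sane values.
#'
#' @param alpha Per-study adjusted-p threshold for a DEG call.
#' @param min_abs_lfc Minimum |log2FC| for a DEG call.
#' @param dep_alpha Raw enrichment-p threshold defining a DEP.
#' @param min_support Vote-counting support threshold (same-direction
#'   studies).
#' @param orthology_policy Passed to [map_genes()].
#' @param universe_policy Passed to [consensus_degs()].
#' @param top_n Size of the top-pathway table.
#' @param gene_scope Passed to [direction_concordance()].
#' @return A validated list of class `pipeline_params`.
#' @export
pipeline_params <- function(alpha = 0.05, min_abs_lfc = 0, dep_alpha = 0.01,
                            min_support = 2,
                            orthology_policy = "one_to_one_only",
                            universe_policy = "intersection",
                            top_n = 10, gene_scope = "shared_degs") {
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0,1]", call. = FALSE)
  if (dep_alpha < 0 || dep_alpha > 1)
    stop("'dep_alpha' must lie in [0,1]", call. = FALSE)
  if (min_abs_lfc < 0) stop("'min_abs_lfc' must be >= 0", call. = FALSE)
  if (min_support < 1) stop("'min_support' must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, min_abs_lfc = min_abs_lfc,
                 dep_alpha = dep_alpha, min_support = as.integer(min_support),
                 orthology_policy = orthology_policy,
                 universe_policy = universe_policy, top_n = top_n,
                 gene_scope = gene_scope),
            class = "pipeline_params")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full cross-species concordance analysis in memory
#'
#' Executes differential expression per human study, the vote-counting
#' consensus, differential expression and ortholog mapping per model,
#' over-representation analysis of the consensus and of each model's DEGs
#' against one gene-set collection, and the concordance scores: pathway- and
#' gene-level recapitulation, Venn partitions, the top-N pathway table,
#' optional biological-category rollups, and gene-direction quadrant
#' concordance.
#'
#' @param studies Named list of [expression_matrix()] objects (human
#'   case/control contrasts), or of `study_de_result` tables.
#' @param models Named list of [expression_matrix()] objects in the model
#'   namespace (model vs control contrasts), or of `study_de_result` tables.
#' @param ortholog_map Data frame `source_id` (model) / `target_id` (human).
#' @param collection A [gene_set_collection()] in the human namespace.
#' @param params A [pipeline_params()].
#' @param categories Optional pathway-to-category assignment (named vector or
#'   `pathway`/`category` data frame) for the category rollup.
#' @return A list of class `concordance_report`; see Details. Key elements:
#'   `consensus`, `human_enrichment`, `model_enrichments`,
#'   `pathway_recapitulation`, `gene_recapitulation`, `venn`, `top_n`,
#'   `category_rollup`, `concordance` (per model
#'   [direction_concordance()] results), `counts` (stage-by-stage tallies).
#' @export
analyze_bundle <- function(studies, models, ortholog_map, collection,
                           params = pipeline_params(), categories = NULL) {
  stopifnot(inherits(params, "pipeline_params"))
  as_de <- function(x, id)
    if (inherits(x, "study_de_result")) x
    else run_de(x, params$alpha, params$min_abs_lfc, study_id = id)

  study_results <- with_stage("diffexpr", {
    out <- lapply(names(studies), function(s) as_de(studies[[s]], s))
    stats::setNames(out, names(studies))
  })
  deg_sets <- lapply(study_results, call_degs, alpha = params$alpha,
                     min_abs_lfc = params$min_abs_lfc)
  consensus <- with_stage("meta_vote",
    consensus_degs(deg_sets, params$min_support, de_results = study_results,
                   universe_policy = params$universe_policy))

  model_results <- with_stage("orthology", {
    out <- lapply(names(models), function(m) {
      res <- as_de(models[[m]], m)
      map_genes(res, ortholog_map, params$orthology_policy)$result
    })
    stats::setNames(out, names(models))
  })
  model_deg_sets <- lapply(model_results, call_degs, alpha = params$alpha,
                           min_abs_lfc = params$min_abs_lfc)

  human_universe <- attr(consensus, "universe")
  human_query <- intersect(consensus_genes(consensus), human_universe)
  human_enr <- with_stage("enrichment",
    enrich(human_query, human_universe, collection, params$dep_alpha))
  human_deps <- dep_list(human_enr)$set
  model_enrs <- with_stage("enrichment", {
    out <- lapply(names(model_results), function(m) {
      res <- model_results[[m]]
      q <- res$gene[res$direction != "none"]
      enrich(q, res$gene, collection, params$dep_alpha)
    })
    stats::setNames(out, names(models))
  })
  model_dep_sets <- lapply(model_enrs, function(e) dep_list(e)$set)

  report <- with_stage("concordance", {
    pathway_recap <- if (length(human_deps))
      recapitulation(human_deps, model_dep_sets) else NULL
    model_gene_sets <- lapply(model_deg_sets, function(d) c(d$up, d$down))
    gene_recap <- if (length(consensus_genes(consensus)))
      recapitulation(consensus_genes(consensus), model_gene_sets) else NULL
    venn <- if (length(models) >= 2L && length(models) <= 3L)
      venn_counts(model_dep_sets) else NULL
    top_n <- if (length(human_deps))
      top_n_table(human_enr, model_enrs, params$top_n) else NULL
    rollup <- if (!is.null(categories) && length(human_deps))
      category_rollup(consensus, model_results, categories, collection,
                      human_deps) else NULL
    concord <- lapply(model_results, function(res)
      tryCatch(direction_concordance(consensus, res, params$gene_scope),
               error = function(e) NULL))
    list(pathway_recapitulation = pathway_recap,
         gene_recapitulation = gene_recap, venn = venn, top_n = top_n,
         category_rollup = rollup, concordance = concord)
  })

  structure(c(list(
    consensus = consensus,
    study_results = study_results,
    model_results = model_results,
    human_enrichment = human_enr,
    model_enrichments = model_enrs,
    params = params,
    counts = list(
      n_studies = length(studies), n_models = length(models),
      degs_per_study = vapply(deg_sets,
                              function(d) length(d$up) + length(d$down),
                              integer(1)),
      n_consensus_genes = length(consensus_genes(consensus)),
      n_conflicted = sum(consensus$conflicted),
      n_human_deps = length(human_deps),
      deps_per_model = vapply(model_dep_sets, length, integer(1)))),
    report), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance_report: %d studies, %d models, %d consensus genes, %d human DEPs\n",
              x$counts$n_studies, x$counts$n_models,
              x$counts$n_consensus_genes, x$counts$n_human_deps))
  if (!is.null(x$pathway_recapitulation)) {
    cat("pathway recapitulation:\n")
    print(as.data.frame(x$pathway_recapitulation))
  }
  invisible(x)
}

report_json_payload <- function(report) {
  concord <- lapply(report$concordance, function(q)
    if (is.null(q)) NULL
    else q[c("percent_concordant", "percent_discordant", "n_pairs",
             "n_zero_excluded")])
  list(counts = report$counts,
       params = unclass(report$params),
       pathway_recapitulation =
         if (!is.null(report$pathway_recapitulation))
           as.data.frame(report$pathway_recapitulation) else NULL,
       gene_recapitulation =
         if (!is.null(report$gene_recapitulation))
           as.data.frame(report$gene_recapitulation) else NULL,
       venn = as.list(report$venn),
       top_n = if (!is.null(report$top_n)) list(
         table = as.data.frame(report$top_n),
         n_recapitulated = as.list(attr(report$top_n, "n_recapitulated")))
         else NULL,
       category_rollup = report$category_rollup,
       direction_concordance = concord)
}

#' Write a concordance report to disk
#'
#' Emits the machine-readable JSON report plus human-readable TSV tables
#' (consensus signature, per-contrast DE tables, DEP tables, recapitulation
#' and rollup tables) under a stable filename scheme, and a run log with the
#' thresholds and stage-by-stage counts.
#'
#' @param report A `concordance_report` from [analyze_bundle()].
#' @param out_dir Output directory (created if missing).
#' @param overwrite Refuse to overwrite an existing report unless `TRUE`.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, overwrite = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  report_path <- file.path(out_dir, "report.json")
  if (file.exists(report_path) && !overwrite)
    stop(sprintf("'%s' exists; set overwrite = TRUE to replace it",
                 report_path), call. = FALSE)
  for (s in names(report$study_results))
    write_de_table(report$study_results[[s]],
                   file.path(out_dir, sprintf("de_%s.tsv", s)))
  for (m in names(report$model_results))
    write_de_table(report$model_results[[m]],
                   file.path(out_dir, sprintf("de_model_%s.tsv", m)))
  write_consensus(report$consensus, file.path(out_dir, "consensus.tsv"))
  utils::write.table(as.data.frame(report$human_enrichment),
                     file.path(out_dir, "enrichment_human.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in names(report$model_enrichments))
    utils::write.table(as.data.frame(report$model_enrichments[[m]]),
                       file.path(out_dir, sprintf("enrichment_%s.tsv", m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report_json_payload(report), report_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_lines <- c(
    "recapitome run log",
    sprintf("package_version: %s",
            as.character(utils::packageVersion("recapitome"))),
    sprintf("thresholds: alpha=%g min_abs_lfc=%g dep_alpha=%g min_support=%d",
            report$params$alpha, report$params$min_abs_lfc,
            report$params$dep_alpha, report$params$min_support),
    sprintf("policies: orthology=%s universe=%s gene_scope=%s",
            report$params$orthology_policy, report$params$universe_policy,
            report$params$gene_scope),
    sprintf("studies: %d (DEGs: %s)", report$counts$n_studies,
            paste(report$counts$degs_per_study, collapse = ", ")),
    sprintf("consensus genes: %d (+%d conflicted, excluded)",
            report$counts$n_consensus_genes, report$counts$n_conflicted),
    sprintf("human DEPs: %d", report$counts$n_human_deps),
    sprintf("model DEPs: %s",
            paste(sprintf("%s=%d", names(report$counts$deps_per_model),
                          report$counts$deps_per_model), collapse = ", ")))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Simulate a complete study bundle on disk
#'
#' Generates the multi-study human data, one model dataset per
#' [model_sim_config()], the ortholog table, a gene-set collection and the
#' ground-truth JSON, writes everything under `out_dir` (gzip TSV matrices,
#' label TSVs, GMT, ortholog TSV, truth JSON) together with a pipeline YAML
#' config, and returns the in-memory objects.
#'
#' @param config A [sim_config()].
#' @param model_cfgs Named list of [model_sim_config()]s.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param n_sets,set_size,enriched_fraction Passed to [generate_genesets()].
#' @param one_to_many_fraction Passed to [generate_ortholog_map()].
#' @return List with `studies`, `models`, `truth`, `collection`,
#'   `ortholog_map`, and (when written) `config_path`.
#' @export
simulate_bundle <- function(config, model_cfgs, out_dir = NULL,
                            n_sets = 40, set_size = 50,
                            enriched_fraction = 0.3,
                            one_to_many_fraction = 0) {
  sim <- simulate_multistudy(config)
  truth <- sim$truth
  models <- list()
  for (m in names(model_cfgs)) {
    md <- simulate_model_dataset(config, model_cfgs[[m]], truth, m)
    truth <- md$truth
    models[[m]] <- md$matrix
  }
  collection <- generate_genesets(truth, n_sets, set_size, enriched_fraction,
                                  seed = config$seed)
  omap <- generate_ortholog_map(truth$universe, one_to_many_fraction,
                                seed = config$seed)
  bundle <- list(studies = sim$studies, models = models, truth = truth,
                 collection = collection, ortholog_map = omap)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- list(studies = list(), models = list())
    for (s in names(sim$studies)) {
      cp <- file.path(out_dir, sprintf("counts_%s.tsv.gz", s))
      lp <- file.path(out_dir, sprintf("labels_%s.tsv", s))
      em <- sim$studies[[s]]
      write_counts_tsv(em$values, cp)
      write_group_labels(em$group, lp, sample_ids = colnames(em$values))
      paths$studies[[s]] <- list(counts = cp, labels = lp)
    }
    for (m in names(models)) {
      cp <- file.path(out_dir, sprintf("counts_model_%s.tsv.gz", m))
      lp <- file.path(out_dir, sprintf("labels_model_%s.tsv", m))
      em <- models[[m]]
      write_counts_tsv(em$values, cp)
      write_group_labels(em$group, lp, sample_ids = colnames(em$values))
      paths$models[[m]] <- list(counts = cp, labels = lp)
    }
    gmt <- file.path(out_dir, "genesets.gmt")
    write_gmt(collection, gmt)
    op <- file.path(out_dir, "ortholog_map.tsv")
    utils::write.table(omap, op, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_truth_json(truth, file.path(out_dir, "truth.json"))
    cfg <- list(studies = paths$studies, models = paths$models,
                genesets = gmt, ortholog_map = op,
                params = unclass(pipeline_params()),
                out_dir = file.path(out_dir, "results"))
    config_path <- file.path(out_dir, "pipeline_config.yaml")
    yaml::write_yaml(cfg, config_path)
    bundle$config_path <- config_path
  }
  bundle
}

#' Run the full pipeline from a configuration file or list
#'
#' Reads the study and model inputs named in the configuration (count
#' matrices plus labels, or pre-computed DE tables), executes
#' diffexpr, meta_vote, orthology, enrichment and concordance, writes every
#' intermediate and the final report under `out_dir`, and returns the report.
#' Any stage error aborts with the stage name; artifacts written before the
#' failure are retained.
#'
#' @param config Path to a YAML config (as written by [simulate_bundle()]) or
#'   an equivalent list: `studies` / `models` (named lists with `counts` +
#'   `labels` or `de_table` paths), `genesets` (GMT path), `ortholog_map`
#'   (TSV path), optional `categories` (TSV `pathway`/`category`), `params`
#'   (see [pipeline_params()]), `out_dir`.
#' @param overwrite Refuse to overwrite an existing report unless `TRUE`.
#' @return The `concordance_report`, invisibly.
#' @export
run_pipeline <- function(config, overwrite = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- do.call(pipeline_params,
                    config$params %||% list())
  load_contrast <- function(entry, id) {
    if (!is.null(entry$de_table))
      ingest_de_table(entry$de_table, params$alpha, params$min_abs_lfc, id)
    else read_expression_matrix(entry$counts, entry$labels)
  }
  studies <- with_stage("io", {
    out <- lapply(names(config$studies), function(s)
      load_contrast(config$studies[[s]], s))
    stats::setNames(out, names(config$studies))
  })
  models <- with_stage("io", {
    out <- lapply(names(config$models), function(m)
      load_contrast(config$models[[m]], m))
    stats::setNames(out, names(config$models))
  })
  collection <- with_stage("io", read_gmt(config$genesets))
  omap <- with_stage("io", read_ortholog_map(config$ortholog_map))
  categories <- if (!is.null(config$categories))
    with_stage("io", utils::read.delim(config$categories,
                                       stringsAsFactors = FALSE)) else NULL
  report <- analyze_bundle(studies, models, omap, collection, params,
                           categories)
  if (!is.null(config$out_dir))
    write_report(report, config$out_dir, overwrite = overwrite)
  invisible(report)
}
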