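# Small simulated fixtures shared across tests; built in code at run time.

tiny_sim_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes = 300, n_studies = 3, samples_per_group = 5,
         signature_size = 40, lfc_magnitude = 1.5, per_study_power = 0.9,
         seed = seed),
    list(...))
  do.call(sim_config, args)
}

toy_expression_matrix <- function(counts, n_case, n_control) {
  colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  expression_matrix(counts, rep(c("case", "control"), c(n_case, n_control)))
}
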