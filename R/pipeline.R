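#' Run the full analysis pipeline on simulated data
#'
#' End-to-end driver used by the numbered analysis scripts and the smoke
#' tests: simulate tree + peak table + response matrix from a
#' [sim_config()], call sex-specific and transferred compounds, estimate
#' per-feature Pagel's lambda for each sex and compare the distributions,
#' build the detection network and contrast at1/at4 clustering
#' coefficients. All randomness flows from `cfg$seed`, so reruns with the
#' same config are reproducible.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as TSV/JSON-like text files (tree Newick, peak table,
#'   response matrix, lambda tables, network edge list, summary).
#' @return List with `tree`, `peak_table`, `catalog`, `truth`,
#'   `lambda` (per-sex feature tables), `sex_test` (`stat_result`),
#'   `network`, `coefficients`, `coef_test`, `self_loops`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  sim <- simulate_peak_table(cfg)
  pt <- sim$peak_table
  catalog <- call_sex_specific(pt)
  catalog <- call_transferred(pt, catalog)

  lambda <- list()
  for (sex in c("male", "female")) {
    tm <- standardize_profiles(pt[pt$sex == sex, , drop = FALSE])
    lambda[[sex]] <- fit_lambda_profile(tm, sim$tree)
  }
  sex_test <- compare_lambda_distributions(lambda$male$lambda_hat,
                                           lambda$female$lambda_hat)

  rsim <- simulate_response_matrix(catalog, cfg)
  net <- build_network(catalog, rsim$response_matrix,
                       threshold = cfg$noise_ceiling)
  cc <- clustering_coefficients(net)
  coef_test <- compare_coefficients(net)
  loops <- self_loop_summary(net)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_newick(sim$tree, file.path(out_dir, "tree.nwk"))
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(pt, "peak_table.tsv")
    wt(rsim$response_matrix, "response_matrix.tsv")
    wt(lambda$male, "lambda_male.tsv")
    wt(lambda$female, "lambda_female.tsv")
    wt(catalog$compounds, "compound_catalog.tsv")
    wt(cc, "clustering_coefficients.tsv")
    write_network(net, file.path(out_dir, "network_edges.tsv"))
    summary_lines <- c(
      sprintf("seed\t%d", cfg$seed),
      sprintf("n_species\t%d", cfg$n_species),
      sprintf("wilcoxon_sex_W\t%g", sex_test$statistic),
      sprintf("wilcoxon_sex_p\t%g", sex_test$p_value),
      sprintf("mannwhitney_at1_at4_p\t%g", coef_test$p_value),
      sprintf("self_loops_at1\t%d", loops$totals[["at1"]]),
      sprintf("self_loops_at4\t%d", loops$totals[["at4"]]))
    writeLines(summary_lines, file.path(out_dir, "summary.tsv"))
  }
  list(tree = sim$tree, peak_table = pt, catalog = catalog,
       truth = sim$truth, lambda = lambda, sex_test = sex_test,
       network = net, coefficients = cc, coef_test = coef_test,
       self_loops = loops)
}
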