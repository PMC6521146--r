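#' Run the full analysis pipeline on a synthetic dataset
#'
#' Generates a dataset from `config`, identifies Yin/Yang genes, fits the
#' per-tumor lasso models on them, selects key regulators per subtype against
#' the permutation null, builds the pathway-filtered regulator-target network
#' (using the planted pathway sets), computes the YMR signature with survival
#' generated from it, and writes every result table as TSV into `out_dir`.
#' All randomness derives from `config$seed`, so two runs with the same
#' configuration produce byte-identical output files for any worker count.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param n_permutations permutation-null size (default 100).
#' @param fdr_cut regulator selection threshold (default 0.05).
#' @param n_workers forked workers for the permutation loop.
#' @return (invisibly) a list with the in-memory results: `sim`, `deg`,
#'   `yinyang`, `selection`, `network`, `signature`.
#' @export
run_pipeline <- function(config, out_dir, n_permutations = 100L,
                         fdr_cut = 0.05, n_workers = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 3L)
  p <- function(f) file.path(out_dir, f)

  sim <- generate_dataset(config)
  ds <- sim$dataset

  deg <- test_differential(ds$expr_tumor, ds$expr_normal)
  yy <- select_yin_yang(deg)
  genes <- sort(c(yy$yin, yy$yang))
  if (length(genes) < 20L) genes <- rownames(ds$expr_tumor)

  sel <- select_regulators(ds, genes = genes, n_permutations = n_permutations,
                           seed = seeds[1L], fdr_cut = fdr_cut,
                           n_workers = n_workers)

  all_selected <- sort(unique(unlist(sel$selected_sets)))
  network <- build_network_table(all_selected, ds$tf_binding,
                                 ds$mirna_binding, sim$truth$pathway_sets,
                                 yin_yang = genes)

  ymr <- ymr_score(ds$expr_tumor, yin = yy$yin, yang = yy$yang)
  z <- as.numeric(scale(ymr)); names(z) <- names(ymr)
  surv <- generate_survival(0.8 * z, hazard_scale = 0.1,
                            censor_rate = config$censor_rate,
                            seed = seeds[2L])
  sig <- evaluate_signature(ymr, surv, cutoff = "mean")

  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    df
  }
  wt <- function(df, file) write.table(fmt(df), p(file), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  wt(yy$records, "deg.tsv")
  write_matrix_tsv(sel$model_set$model_matrix, p("model_matrix.tsv"), "tumor")
  wt(data.frame(tumor = names(sel$model_set$lambda),
                lambda = unname(sel$model_set$lambda),
                cv_spearman = unname(sel$model_set$cv_spearman),
                subtype = as.character(ds$subtype),
                stringsAsFactors = FALSE), "model_metrics.tsv")
  wt(sel$result, "regulator_scores.tsv")
  wt(sel$shared, "regulator_groups.tsv")
  wt(network, "network.tsv")
  write_sif(network, p("network.sif"))
  wt(sig$table, "signature.tsv")
  wt(sig$km, "km.tsv")
  wt(data.frame(statistic = sig$logrank$statistic, p = sig$logrank$p),
     "logrank.tsv")
  write_survival_tsv(surv, p("survival.tsv"))

  invisible(list(sim = sim, deg = deg, yinyang = yy, selection = sel,
                 network = network, signature = sig))
}
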