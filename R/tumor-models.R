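# Shared assembly of per-tumor model inputs: response matrix, imputed
# covariate matrices, per-tumor miRNA fold changes and admitted-miRNA sets.
prepare_model_inputs <- function(dataset, genes = NULL, mirna_threshold = 0) {
  stopifnot(inherits(dataset, "omics_dataset"))
  all_genes <- rownames(dataset$expr_tumor)
  if (is.null(genes)) genes <- all_genes
  missing <- setdiff(genes, all_genes)
  if (length(missing))
    stop("genes not in dataset: ", paste(head(missing, 5L), collapse = ", "))
  genes <- sort(genes)
  tumors <- colnames(dataset$expr_tumor)

  y <- tumor_fold_changes(dataset$expr_tumor, dataset$expr_normal, genes)
  mirna_fc <- tumor_fold_changes(dataset$mirna_tumor, dataset$mirna_normal)

  cnv <- impute_row_means(dataset$cnv[genes, , drop = FALSE])
  meth <- impute_row_means(dataset$methylation[genes, , drop = FALSE])
  tf <- dataset$tf_binding[genes, sort(colnames(dataset$tf_binding)), drop = FALSE]
  mir <- dataset$mirna_binding[genes, sort(colnames(dataset$mirna_binding)), drop = FALSE]

  admitted <- lapply(tumors, function(k) {
    fc <- mirna_fc[colnames(mir), k]
    which(!is.na(fc) & abs(fc) > mirna_threshold)
  })
  names(admitted) <- tumors

  list(genes = genes, tumors = tumors, y = y, cnv = cnv, meth = meth,
       tf = tf, mir = mir, mirna_fc = mirna_fc, admitted = admitted,
       mirna_threshold = mirna_threshold,
       feature_names = c("CNV", "DM", colnames(tf), colnames(mir)))
}

assemble_design <- function(inputs, tumor) {
  adm <- inputs$admitted[[tumor]]
  X <- cbind(CNV = inputs$cnv[, tumor],
             DM = inputs$meth[, tumor],
             inputs$tf,
             inputs$mir[, adm, drop = FALSE])
  if (ncol(X) == 0L) stop("no admitted features for tumor ", tumor)
  X
}

#' Build one tumor's design matrix
#'
#' Rows are the modelled (Yin/Yang) genes; columns are, in order, the tumor's
#' gene-level copy number (CNV), methylation beta (DM), all TF binding-site
#' counts (sorted by TF id) and the binding-site counts of the admitted
#' miRNAs (sorted by miRNA id). A miRNA is admitted for a tumor when its
#' tumor-versus-normal log2 fold change is non-missing and exceeds
#' `mirna_threshold` in magnitude. Missing CNV/methylation entries are
#' mean-imputed per gene across tumors.
#'
#' @param dataset an [omics_dataset()].
#' @param tumor tumor sample id.
#' @param genes genes to model (default: all dataset genes).
#' @param mirna_threshold miRNA fold-change admission threshold (default 0:
#'   any miRNA with a measured nonzero fold change).
#' @return genes x features numeric matrix.
#' @export
build_design <- function(dataset, tumor, genes = NULL, mirna_threshold = 0) {
  stopifnot(tumor %in% colnames(dataset$expr_tumor))
  inputs <- prepare_model_inputs(dataset, genes, mirna_threshold)
  assemble_design(inputs, tumor)
}

#' Fit all per-tumor lasso models of a dataset
#'
#' Fits one lasso model per tumor (penalty by 10-fold CV over genes) and
#' assembles the tumor x feature coefficient matrix over the full feature set
#' `CNV, DM, TFs, miRNAs`, with structural zeros for miRNAs not admitted in a
#' given tumor.
#'
#' @inheritParams build_design
#' @param n_folds CV folds per tumor (default 10).
#' @param seed master seed; each tumor's fold shuffle uses its own substream.
#' @return object of class `tumor_model_set`: `model_matrix` (tumors x
#'   features), `intercepts`, `lambda`, `cv_spearman` (per tumor), `subtype`,
#'   `genes`, `mirna_threshold`.
#' @export
fit_all_tumors <- function(dataset, genes = NULL, mirna_threshold = 0,
                           n_folds = 10L, seed = 1) {
  inputs <- prepare_model_inputs(dataset, genes, mirna_threshold)
  tumors <- inputs$tumors
  seeds <- derive_seeds(seed, length(tumors))
  feats <- inputs$feature_names

  W <- matrix(0, length(tumors), length(feats), dimnames = list(tumors, feats))
  a0 <- setNames(numeric(length(tumors)), tumors)
  lam <- setNames(numeric(length(tumors)), tumors)
  cvsp <- setNames(numeric(length(tumors)), tumors)

  for (i in seq_along(tumors)) {
    k <- tumors[i]
    X <- assemble_design(inputs, k)
    fit <- fit_tumor_lasso(X, inputs$y[, k], n_folds = n_folds, seed = seeds[i])
    W[k, colnames(X)] <- fit$coefficients
    a0[k] <- fit$intercept
    lam[k] <- fit$lambda
    cvsp[k] <- fit$cv_spearman
  }
  structure(list(model_matrix = W, intercepts = a0, lambda = lam,
                 cv_spearman = cvsp, subtype = dataset$subtype,
                 genes = inputs$genes, mirna_threshold = mirna_threshold,
                 n_folds = n_folds, seed = seed),
            class = "tumor_model_set")
}

#' @export
print.tumor_model_set <- function(x, ...) {
  cat("tumor model set:", nrow(x$model_matrix), "tumors x",
      ncol(x$model_matrix), "features;",
      "mean CV Spearman =", signif(mean(x$cv_spearman), 3), "\n")
  invisible(x)
}

default_feature_subsets <- function() {
  list("miRNA" = "mir",
       "miRNA+TF" = c("mir", "tf"),
       "miRNA+TF+CNV" = c("mir", "tf", "cnv"),
       "miRNA+TF+CNV+DM" = c("mir", "tf", "cnv", "dm"))
}

subset_columns <- function(inputs, tumor, blocks) {
  parts <- list()
  if ("cnv" %in% blocks) parts$CNV <- inputs$cnv[, tumor]
  if ("dm" %in% blocks) parts$DM <- inputs$meth[, tumor]
  X <- do.call(cbind, parts)
  if ("tf" %in% blocks) X <- cbind(X, inputs$tf)
  if ("mir" %in% blocks)
    X <- cbind(X, inputs$mir[, inputs$admitted[[tumor]], drop = FALSE])
  X
}

#' Held-out predictive performance of nested feature subsets
#'
#' For each tumor and each feature subset, runs a 10-fold CV over genes
#' (training on 90% of the genes, predicting the held-out 10%) and reports
#' the mean held-out Spearman rank correlation between predicted and observed
#' fold changes at the CV-selected penalty. The fold assignment is seeded and
#' shared across subsets so per-tumor correlations are paired.
#'
#' @inheritParams fit_all_tumors
#' @param feature_subsets named list of block combinations (blocks among
#'   `"mir"`, `"tf"`, `"cnv"`, `"dm"`); defaults to the nested ladder
#'   miRNA, miRNA+TF, miRNA+TF+CNV, miRNA+TF+CNV+DM.
#' @return tumors x subsets matrix of mean held-out Spearman correlations.
#' @export
cross_validate_features <- function(dataset, genes = NULL,
                                    feature_subsets = default_feature_subsets(),
                                    n_folds = 10L, seed = 1,
                                    mirna_threshold = 0) {
  inputs <- prepare_model_inputs(dataset, genes, mirna_threshold)
  tumors <- inputs$tumors
  seeds <- derive_seeds(seed, length(tumors))
  out <- matrix(NA_real_, length(tumors), length(feature_subsets),
                dimnames = list(tumors, names(feature_subsets)))
  nG <- length(inputs$genes)
  for (i in seq_along(tumors)) {
    k <- tumors[i]
    foldid <- with_seed(seeds[i], sample(rep_len(seq_len(n_folds), nG)))
    for (s in seq_along(feature_subsets)) {
      X <- subset_columns(inputs, k, feature_subsets[[s]])
      cv <- cv_lasso(X, inputs$y[, k], n_folds = n_folds, foldid = foldid)
      out[k, s] <- cv$cv_spearman
    }
  }
  out
}

#' Paired comparison of per-tumor CV correlations
#'
#' Two-sided (by default) Wilcoxon signed-rank test on paired per-tumor
#' correlation vectors from [cross_validate_features()].
#'
#' @param corrs_a,corrs_b paired numeric vectors (same tumors, same order).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return the p-value.
#' @export
compare_models <- function(corrs_a, corrs_b, alternative = "two.sided") {
  stopifnot(length(corrs_a) == length(corrs_b))
  d <- corrs_a - corrs_b
  if (all(d == 0)) return(1)
  suppressWarnings(
    wilcox.test(corrs_a, corrs_b, paired = TRUE,
                alternative = alternative)$p.value
  )
}

#' Randomized-response baseline correlations
#'
#' Permutes the gene labels of each tumor's fold-change response (its own
#' substream of the seed), then runs the identical full-feature CV procedure.
#' The resulting per-tumor correlations form the chance baseline against
#' which the real models are compared.
#'
#' @inheritParams cross_validate_features
#' @return named per-tumor vector of mean held-out Spearman correlations
#'   under the permuted response.
#' @export
randomized_baseline <- function(dataset, genes = NULL, n_folds = 10L, seed = 1,
                                mirna_threshold = 0) {
  inputs <- prepare_model_inputs(dataset, genes, mirna_threshold)
  tumors <- inputs$tumors
  seeds <- derive_seeds(seed, 2L * length(tumors))
  nG <- length(inputs$genes)
  out <- setNames(numeric(length(tumors)), tumors)
  for (i in seq_along(tumors)) {
    k <- tumors[i]
    yperm <- with_seed(seeds[2L * i - 1L], inputs$y[sample.int(nG), k])
    foldid <- with_seed(seeds[2L * i], sample(rep_len(seq_len(n_folds), nG)))
    X <- assemble_design(inputs, k)
    cv <- cv_lasso(X, yperm, n_folds = n_folds, foldid = foldid)
    out[k] <- cv$cv_spearman
  }
  out
}
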