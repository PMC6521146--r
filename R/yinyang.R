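#' Tumor-versus-normal differential expression per gene
#'
#' Per gene, computes the log2 fold change (mean tumor minus mean normal on
#' the log2 scale), a two-sided Welch t-test p-value, and a
#' Benjamini-Hochberg FDR over all tested genes. Genes with fewer than two
#' non-missing values in either group are untestable and excluded.
#'
#' @param tumor_expr,normal_expr gene x sample matrices on the log2 scale
#'   (shared gene rows).
#' @return data frame with columns gene, logFC, p, fdr, ordered as the input
#'   genes (untestable genes dropped; their ids are kept in the
#'   `"untestable"` attribute).
#' @export
test_differential <- function(tumor_expr, normal_expr) {
  genes <- intersect(rownames(tumor_expr), rownames(normal_expr))
  stopifnot(length(genes) > 0L)
  tm <- as.matrix(tumor_expr)[genes, , drop = FALSE]
  nm <- as.matrix(normal_expr)[genes, , drop = FALSE]

  n1 <- rowSums(!is.na(tm)); n2 <- rowSums(!is.na(nm))
  testable <- n1 >= 2L & n2 >= 2L
  untestable <- genes[!testable]
  tm <- tm[testable, , drop = FALSE]; nm <- nm[testable, , drop = FALSE]
  n1 <- n1[testable]; n2 <- n2[testable]

  m1 <- rowMeans(tm, na.rm = TRUE); m2 <- rowMeans(nm, na.rm = TRUE)
  v1 <- apply(tm, 1L, var, na.rm = TRUE); v2 <- apply(nm, 1L, var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  # Welch-Satterthwaite degrees of freedom
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)

  out <- data.frame(gene = genes[testable], logFC = m1 - m2, p = p,
                    fdr = p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "untestable") <- untestable
  out
}

#' Select Yin and Yang genes from differential-expression records
#'
#' Yin genes are significantly upregulated (FDR below `fdr_cut` and logFC of
#' at least `lfc_cut`); Yang genes are significantly downregulated (logFC of
#' at most `-lfc_cut`). Both logFC boundaries are inclusive.
#'
#' @param records data frame from [test_differential()].
#' @param fdr_cut FDR threshold (default 0.05, strict `<`).
#' @param lfc_cut absolute log2-fold-change threshold (default 1, inclusive).
#' @return list with `yin`, `yang` (character vectors) and `records` (the
#'   input with a `yclass` column over Yin / Yang / none).
#' @export
select_yin_yang <- function(records, fdr_cut = 0.05, lfc_cut = 1) {
  stopifnot(all(c("gene", "logFC", "fdr") %in% names(records)))
  sig <- records$fdr < fdr_cut
  yclass <- rep("none", nrow(records))
  yclass[sig & records$logFC >= lfc_cut] <- "Yin"
  yclass[sig & records$logFC <= -lfc_cut] <- "Yang"
  records$yclass <- yclass
  list(yin = records$gene[yclass == "Yin"],
       yang = records$gene[yclass == "Yang"],
       records = records)
}

#' Per-tumor expression fold changes against the mean normal profile
#'
#' The response of the per-tumor models: for each gene (or miRNA) and tumor,
#' the tumor's log2 expression minus the mean log2 expression over all
#' normal samples.
#'
#' @param tumor_expr,normal_expr feature x sample matrices on the log2 scale.
#' @param features features to compute (default: all shared rows); every
#'   requested feature must be present in both matrices.
#' @return feature x tumor fold-change matrix.
#' @export
tumor_fold_changes <- function(tumor_expr, normal_expr, features = NULL) {
  tm <- as.matrix(tumor_expr); nm <- as.matrix(normal_expr)
  if (is.null(features)) features <- intersect(rownames(tm), rownames(nm))
  missing_t <- setdiff(features, rownames(tm))
  missing_n <- setdiff(features, rownames(nm))
  if (length(missing_n))
    stop("features absent from the normal matrix: ",
         paste(head(missing_n, 5L), collapse = ", "))
  if (length(missing_t))
    stop("features absent from the tumor matrix: ",
         paste(head(missing_t, 5L), collapse = ", "))
  ref <- rowMeans(nm[features, , drop = FALSE], na.rm = TRUE)
  tm[features, , drop = FALSE] - ref
}
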