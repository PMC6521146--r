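#' Log2(x + 1) transform of expression values
#'
#' Transforms raw RSEM (gene) or RPM (miRNA) quantifications to the
#' log2(x + 1) scale on which all downstream modelling operates. The result
#' carries a unit tag; re-applying the transform to already-transformed data
#' is refused.
#'
#' @param raw nonnegative numeric matrix (missing values allowed).
#' @param unit unit tag, `"gene-RSEM"` or `"miRNA-RPM"`.
#' @return matrix of class `yy_expr` on the log2(x + 1) scale.
#' @export
log_transform <- function(raw, unit = c("gene-RSEM", "miRNA-RPM")) {
  unit <- match.arg(unit)
  if (inherits(raw, "yy_expr"))
    stop("input is already log2-transformed (unit tag ", attr(raw, "unit"), ")")
  stopifnot(is.matrix(raw))
  if (any(raw < 0, na.rm = TRUE)) stop("negative expression values are not allowed")
  out <- log2(raw + 1)
  expr_matrix(out, unit)
}

expr_matrix <- function(x, unit) {
  structure(x, unit = unit, class = c("yy_expr", class(x)))
}

#' @export
print.yy_expr <- function(x, ...) {
  cat("log2-scale expression matrix [", attr(x, "unit"), "]: ",
      nrow(x), " features x ", ncol(x), " samples\n", sep = "")
  print(unclass(head(x[, seq_len(min(ncol(x), 6L)), drop = FALSE])), ...)
  invisible(x)
}

#' Aggregate miRNA isoform expression to mature strands
#'
#' Per sample, RPM values of all isoforms of the same mature miRNA strand are
#' summed, then transformed to log2(total RPM + 1).
#'
#' @param isoform_rpm data frame with columns `isoform`, `mature_id`,
#'   `sample`, `rpm`.
#' @return mature-miRNA x sample matrix of class `yy_expr` (unit miRNA-RPM).
#' @export
aggregate_mirna_isoforms <- function(isoform_rpm) {
  req <- c("isoform", "mature_id", "sample", "rpm")
  stopifnot(all(req %in% names(isoform_rpm)))
  if (any(isoform_rpm$rpm < 0, na.rm = TRUE)) stop("RPM values must be >= 0")
  key <- paste(isoform_rpm$isoform, isoform_rpm$sample, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (isoform, sample) rows in isoform table")
  agg <- tapply(isoform_rpm$rpm,
                list(mature = isoform_rpm$mature_id, sample = isoform_rpm$sample),
                sum)
  m <- log2(as.matrix(agg) + 1)
  expr_matrix(m, "miRNA-RPM")
}

#' Remove features with excessive missingness
#'
#' Drops rows whose fraction of missing values across all supplied samples is
#' strictly greater than `max_missing_fraction` (a row missing exactly the
#' threshold fraction is kept).
#'
#' @param mat feature x sample matrix.
#' @param max_missing_fraction maximum tolerated missing fraction (default 0.5).
#' @return the filtered matrix (attributes preserved).
#' @export
filter_missing <- function(mat, max_missing_fraction = 0.5) {
  stopifnot(is.matrix(mat), nrow(mat) > 0L)
  frac <- rowMeans(is.na(mat))
  keep <- frac <= max_missing_fraction
  out <- mat[keep, , drop = FALSE]
  if (inherits(mat, "yy_expr")) out <- expr_matrix(out, attr(mat, "unit"))
  out
}

#' Average probe-level methylation beta values per gene
#'
#' When several probes map to the same gene, their beta values are averaged
#' arithmetically per sample.
#'
#' @param probe_betas data frame with columns `probe`, `gene`, `sample`,
#'   `beta` (beta in \[0, 1\]).
#' @return gene x sample matrix of beta values.
#' @export
average_gene_methylation <- function(probe_betas) {
  req <- c("probe", "gene", "sample", "beta")
  stopifnot(all(req %in% names(probe_betas)))
  b <- probe_betas$beta
  if (any(b < 0 | b > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  agg <- tapply(b, list(gene = probe_betas$gene, sample = probe_betas$sample),
                mean, na.rm = TRUE)
  m <- as.matrix(agg)
  m[is.nan(m)] <- NA_real_
  m
}

#' Assign IHC-based molecular subtype
#'
#' Receptor-status rules: luminal A if (ER+ or PR+) and HER2-; luminal B if
#' (ER+ or PR+) and HER2+; Her2-enriched if ER- and PR- and HER2+;
#' triple-negative if all three are negative. Any missing or equivocal status
#' yields `"unclassified"`; such patients are excluded downstream.
#'
#' @param er,pr,her2 character vectors of receptor statuses, `"+"` or `"-"`;
#'   anything else (including `NA`) is treated as missing/equivocal.
#' @return character vector over
#'   `c("LumA", "LumB", "Her2", "TN", "unclassified")`.
#' @export
assign_subtype <- function(er, pr, her2) {
  n <- length(er)
  stopifnot(length(pr) == n, length(her2) == n)
  known <- function(x) !is.na(x) & x %in% c("+", "-")
  pos <- function(x) !is.na(x) & x == "+"
  neg <- function(x) !is.na(x) & x == "-"
  out <- rep("unclassified", n)
  ok <- known(er) & known(pr) & known(her2)
  hrpos <- pos(er) | pos(pr)
  out[ok & hrpos & neg(her2)] <- "LumA"
  out[ok & hrpos & pos(her2)] <- "LumB"
  out[ok & neg(er) & neg(pr) & pos(her2)] <- "Her2"
  out[ok & neg(er) & neg(pr) & neg(her2)] <- "TN"
  out
}

#' Map ChIP-seq peaks to promoter windows
#'
#' The promoter of a gene is the window from `upstream` bp upstream to
#' `downstream` bp downstream of its TSS (defaults 2000 / 200). In 0-based
#' half-open coordinates the window is `[t - upstream, t + downstream)` on the
#' + strand and `[t - downstream, t + upstream)` on the - strand. A peak is
#' assigned to a promoter if the two intervals overlap by at least one base;
#' the matrix cell for a (gene, regulator) pair is the mean score over all
#' overlapping peaks of that regulator, and 0 if there is none.
#'
#' @param peaks data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `regulator`, `score`, `strand`.
#' @param tss data frame with columns `gene`, `chrom`, `position` (0-based
#'   TSS coordinate), `strand`.
#' @param upstream,downstream promoter window extents in bp.
#' @return gene x regulator binding matrix (mean peak score per pair).
#' @export
map_peaks_to_promoters <- function(peaks, tss, upstream = 2000, downstream = 200) {
  stopifnot(all(c("chrom", "start", "end", "regulator", "score", "strand") %in% names(peaks)),
            all(c("gene", "chrom", "position", "strand") %in% names(tss)))
  if (!all(tss$strand %in% c("+", "-")))
    stop("unknown strand in TSS table (must be '+' or '-')")
  if (!all(peaks$strand %in% c("+", "-", "*", ".")))
    stop("unknown strand in peak table")
  if (any(peaks$start < 0) || any(peaks$start >= peaks$end))
    stop("peaks must satisfy 0 <= start < end")

  t0 <- tss$position
  prom_start0 <- ifelse(tss$strand == "+", t0 - upstream, t0 - downstream)
  prom_end0 <- ifelse(tss$strand == "+", t0 + downstream, t0 + upstream)

  # convert 0-based half-open [s, e) to 1-based closed [s + 1, e]
  prom <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = prom_start0 + 1L, end = prom_end0)
  )
  pk <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  hits <- GenomicRanges::findOverlaps(prom, pk, minoverlap = 1L,
                                      ignore.strand = TRUE)

  genes <- as.character(tss$gene)
  regs <- sort(unique(as.character(peaks$regulator)))
  mat <- matrix(0, nrow = length(genes), ncol = length(regs),
                dimnames = list(genes, regs))
  if (length(hits)) {
    gi <- S4Vectors::queryHits(hits)
    ri <- match(peaks$regulator[S4Vectors::subjectHits(hits)], regs)
    sc <- peaks$score[S4Vectors::subjectHits(hits)]
    cell <- (ri - 1L) * length(genes) + gi
    sums <- tapply(sc, cell, sum)
    cnts <- tapply(sc, cell, length)
    idx <- as.integer(names(sums))
    mat[idx] <- as.numeric(sums) / as.numeric(cnts)
  }
  mat
}

#' Assemble an aligned multi-omics dataset
#'
#' Intersects the sample, gene and miRNA identifier sets of the per-platform
#' matrices and returns an [omics_dataset()] restricted and reordered (sorted
#' ids) to the common index sets. The result is independent of the order in
#' which components were supplied.
#'
#' @param expr_tumor,expr_normal gene x sample log2 expression matrices.
#' @param mirna_tumor,mirna_normal miRNA x sample log2 expression matrices.
#' @param cnv gene x tumor GISTIC2 copy-number matrix.
#' @param methylation gene x tumor beta-value matrix.
#' @param tf_binding gene x TF binding-site count matrix.
#' @param mirna_binding gene x miRNA binding-site count matrix.
#' @param subtype named character vector of tumor subtype labels.
#' @return an `omics_dataset`.
#' @export
intersect_common <- function(expr_tumor, expr_normal, mirna_tumor, mirna_normal,
                             cnv, methylation, tf_binding, mirna_binding,
                             subtype) {
  genes <- sort(Reduce(intersect, list(
    rownames(expr_tumor), rownames(cnv), rownames(methylation),
    rownames(tf_binding), rownames(mirna_binding), rownames(expr_normal)
  )))
  tumors <- sort(Reduce(intersect, list(
    colnames(expr_tumor), colnames(cnv), colnames(methylation),
    colnames(mirna_tumor), names(subtype)
  )))
  mirnas <- sort(intersect(rownames(mirna_tumor),
                           intersect(colnames(mirna_binding), rownames(mirna_normal))))
  if (length(genes) == 0L) stop("empty gene intersection across platforms")
  if (length(tumors) == 0L) stop("empty tumor sample intersection across platforms")
  if (length(mirnas) == 0L) stop("empty miRNA intersection across platforms")

  normals <- sort(colnames(expr_normal))
  mirna_normals <- sort(colnames(mirna_normal))
  tfs <- sort(colnames(tf_binding))
  omics_dataset(
    expr_tumor = unclass_mat(expr_tumor)[genes, tumors, drop = FALSE],
    expr_normal = unclass_mat(expr_normal)[genes, normals, drop = FALSE],
    mirna_tumor = unclass_mat(mirna_tumor)[mirnas, tumors, drop = FALSE],
    mirna_normal = unclass_mat(mirna_normal)[mirnas, mirna_normals, drop = FALSE],
    cnv = cnv[genes, tumors, drop = FALSE],
    methylation = methylation[genes, tumors, drop = FALSE],
    tf_binding = tf_binding[genes, tfs, drop = FALSE],
    mirna_binding = mirna_binding[genes, mirnas, drop = FALSE],
    subtype = subtype[tumors]
  )
}

unclass_mat <- function(x) {
  attr(x, "unit") <- NULL
  class(x) <- "matrix"
  # restore implicit array class set
  unclass(as.matrix(x))
}

#' Aligned multi-omics dataset container
#'
#' Bundles tumor and normal expression, miRNA expression, copy number,
#' methylation, the two binding matrices and per-tumor subtype labels over
#' shared gene / tumor / miRNA index sets, with validation of the shared
#' invariants (methylation in \[0, 1\], nonnegative binding counts, aligned
#' dimnames).
#'
#' @param expr_tumor,expr_normal gene x sample log2 expression matrices.
#' @param mirna_tumor,mirna_normal miRNA x sample log2 expression matrices.
#' @param cnv gene x tumor copy-number matrix (GISTIC2 scores).
#' @param methylation gene x tumor beta-value matrix.
#' @param tf_binding gene x TF nonnegative binding matrix.
#' @param mirna_binding gene x miRNA nonnegative binding matrix.
#' @param subtype named character vector over the tumor samples.
#' @return object of class `omics_dataset` (a validated list).
#' @export
omics_dataset <- function(expr_tumor, expr_normal, mirna_tumor, mirna_normal,
                          cnv, methylation, tf_binding, mirna_binding, subtype) {
  ds <- structure(
    list(expr_tumor = expr_tumor, expr_normal = expr_normal,
         mirna_tumor = mirna_tumor, mirna_normal = mirna_normal,
         cnv = cnv, methylation = methylation,
         tf_binding = tf_binding, mirna_binding = mirna_binding,
         subtype = subtype),
    class = "omics_dataset"
  )
  validate_omics_dataset(ds)
}

validate_omics_dataset <- function(ds) {
  genes <- rownames(ds$expr_tumor)
  tumors <- colnames(ds$expr_tumor)
  mirnas <- rownames(ds$mirna_tumor)
  if (anyDuplicated(genes) || anyDuplicated(tumors) || anyDuplicated(mirnas))
    stop("gene / sample / miRNA identifiers must be unique")
  for (nm in c("cnv", "methylation", "tf_binding", "mirna_binding", "expr_normal")) {
    if (!identical(rownames(ds[[nm]]), genes))
      stop("component '", nm, "' is not aligned to the common gene set")
  }
  for (nm in c("cnv", "methylation")) {
    if (!identical(colnames(ds[[nm]]), tumors))
      stop("component '", nm, "' is not aligned to the common tumor set")
  }
  if (!identical(colnames(ds$mirna_tumor), tumors))
    stop("miRNA tumor expression is not aligned to the common tumor set")
  if (!identical(colnames(ds$mirna_binding), mirnas) ||
      !identical(rownames(ds$mirna_normal), mirnas))
    stop("miRNA components are not aligned to the common miRNA set")
  if (!identical(names(ds$subtype), tumors))
    stop("subtype labels are not aligned to the common tumor set")
  if (any(ds$methylation < 0 | ds$methylation > 1, na.rm = TRUE))
    stop("methylation beta values must lie in [0, 1]")
  if (any(ds$tf_binding < 0, na.rm = TRUE) || any(ds$mirna_binding < 0, na.rm = TRUE))
    stop("binding-site counts must be nonnegative")
  ds
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("omics_dataset:",
      nrow(x$expr_tumor), "genes x", ncol(x$expr_tumor), "tumors,",
      ncol(x$expr_normal), "normals,",
      nrow(x$mirna_tumor), "miRNAs,",
      ncol(x$tf_binding), "TFs\n")
  cat("subtypes:", paste(sprintf("%s=%d", names(table(x$subtype)),
                                 table(x$subtype)), collapse = ", "), "\n")
  invisible(x)
}

#' Mean-impute missing values per feature
#'
#' Replaces missing entries of each row by the row mean over non-missing
#' samples (rows with no observed value become 0). Used to complete design
#' rows before lasso fitting.
#'
#' @param mat feature x sample matrix.
#' @return matrix without missing values.
#' @export
impute_row_means <- function(mat) {
  if (!anyNA(mat)) return(mat)
  rm <- rowMeans(mat, na.rm = TRUE)
  rm[is.nan(rm)] <- 0
  idx <- which(is.na(mat), arr.ind = TRUE)
  mat[idx] <- rm[idx[, 1L]]
  mat
}

#' Write / read an omics dataset as a directory of TSV files
#'
#' Emits the same TSV layouts the individual readers consume: one matrix file
#' per platform plus a two-column subtype table. `read_dataset` reassembles
#' and re-validates the dataset; the round trip is lossless.
#'
#' @param ds an `omics_dataset`.
#' @param dir directory (created if needed).
#' @return `read_dataset` returns the reassembled `omics_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(unclass_mat(ds$expr_tumor), p("expr_tumor.tsv"), "gene")
  write_matrix_tsv(unclass_mat(ds$expr_normal), p("expr_normal.tsv"), "gene")
  write_matrix_tsv(unclass_mat(ds$mirna_tumor), p("mirna_tumor.tsv"), "mirna")
  write_matrix_tsv(unclass_mat(ds$mirna_normal), p("mirna_normal.tsv"), "mirna")
  write_matrix_tsv(ds$cnv, p("cnv.tsv"), "gene")
  write_matrix_tsv(ds$methylation, p("methylation.tsv"), "gene")
  write_matrix_tsv(ds$tf_binding, p("tf_binding.tsv"), "gene")
  write_matrix_tsv(ds$mirna_binding, p("mirna_binding.tsv"), "gene")
  write_subtype_tsv(ds$subtype, p("subtype.tsv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  omics_dataset(
    expr_tumor = read_matrix_tsv(p("expr_tumor.tsv")),
    expr_normal = read_matrix_tsv(p("expr_normal.tsv")),
    mirna_tumor = read_matrix_tsv(p("mirna_tumor.tsv")),
    mirna_normal = read_matrix_tsv(p("mirna_normal.tsv")),
    cnv = read_matrix_tsv(p("cnv.tsv")),
    methylation = read_matrix_tsv(p("methylation.tsv")),
    tf_binding = read_matrix_tsv(p("tf_binding.tsv")),
    mirna_binding = read_matrix_tsv(p("mirna_binding.tsv")),
    subtype = read_subtype_tsv(p("subtype.tsv"))
  )
}
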