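#' Read and write Xena-style TSV matrices
#'
#' Matrices are stored tab-separated with a header row; the first column holds
#' the feature (gene / miRNA / regulator) identifier, the remaining columns are
#' samples or regulators. Numeric values are written with 17 significant
#' digits so that a write/read round trip reproduces doubles exactly.
#'
#' @param x numeric matrix with row and column names.
#' @param path file path.
#' @param id_name header label for the identifier column.
#' @return `read_matrix_tsv` returns a numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(x, path, id_name = "id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  body <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  body[is.na(x)] <- "NA"
  lines <- c(
    paste(c(id_name, colnames(x)), collapse = "\t"),
    paste(rownames(x), apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Read and write two-column subtype tables
#'
#' A subtype table has columns `sample` and `subtype`.
#'
#' @param subtype named character vector (names = tumor sample ids).
#' @param path file path.
#' @return `read_subtype_tsv` returns a named character vector.
#' @export
write_subtype_tsv <- function(subtype, path) {
  stopifnot(!is.null(names(subtype)))
  df <- data.frame(sample = names(subtype), subtype = as.character(subtype))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subtype_tsv
#' @export
read_subtype_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.character(df$subtype), df$sample)
}

#' Read and write survival tables
#'
#' Survival tables have columns `id`, `time` (follow-up, years), `event`
#' (1 = event observed, 0 = censored) and optionally `endpoint`
#' (OS / DSS / PFI / DFI).
#'
#' @param surv data frame with columns id, time, event (and optional endpoint).
#' @param path file path.
#' @return `read_survival_tsv` returns the survival data frame.
#' @export
write_survival_tsv <- function(surv, path) {
  stopifnot(all(c("id", "time", "event") %in% names(surv)))
  out <- surv
  out$time <- sprintf("%.17g", surv$time)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_survival(df)
  df
}

validate_survival <- function(surv) {
  stopifnot(all(c("id", "time", "event") %in% names(surv)))
  if (any(!is.finite(surv$time)) || any(surv$time < 0))
    stop("survival times must be finite and >= 0")
  if (!all(surv$event %in% c(0, 1)))
    stop("event indicator must be 0 (censored) or 1 (event)")
  invisible(surv)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT layout: one set per line, tab-separated
#' `name <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param sets named list of character vectors of gene ids.
#' @param path file path.
#' @param descriptions optional character vector of set descriptions.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  sets
}

#' Read BED6 peak files
#'
#' Reads ChIP-seq peaks in BED6 layout (chrom, start, end, name, score,
#' strand; 0-based half-open coordinates) into the peak data frame consumed by
#' [map_peaks_to_promoters()]. The `name` column carries the regulator id.
#' Uses rtracklayer for parsing when available.
#'
#' @param path BED file path.
#' @return data frame with columns chrom, start, end, regulator, score, strand
#'   (start/end 0-based half-open).
#' @export
read_peaks_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      regulator = as.character(gr$name),
      score = as.numeric(gr$score),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    stopifnot(ncol(df) >= 6L)
    names(df)[1:6] <- c("chrom", "start", "end", "regulator", "score", "strand")
    df[, 1:6]
  }
}

#' Write a Cytoscape-importable SIF edge list
#'
#' Rows of the network edge table become `source targets target` lines.
#'
#' @param edges network edge table from [build_network_table()].
#' @param path file path.
#' @export
write_sif <- function(edges, path) {
  stopifnot(all(c("regulator", "target") %in% names(edges)))
  writeLines(paste(edges$regulator, "targets", edges$target, sep = "\t"), path)
  invisible(path)
}
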