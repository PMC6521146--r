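#' Hypergeometric gene-set over-representation test
#'
#' For each gene set of size within `[min_size, max_size]` (after restriction
#' to the universe), computes the upper-tail hypergeometric probability of
#' observing at least the realised overlap between the target list and the
#' set, then adjusts over the tested sets with Benjamini-Hochberg. The
#' default universe is the union of all genes appearing in the collection.
#' Canonical-pathway analyses use `min_size = 2`; GO biological-process
#' analyses use `min_size = 10` (both with `max_size = 500`).
#'
#' @param targets character vector of target gene ids; genes outside the
#'   universe are dropped with a warning.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param universe annotatable gene universe (default: union of the
#'   collection's sets).
#' @param min_size,max_size tested set-size bounds (defaults 2 / 500).
#' @return data frame (set, overlap k, n_targets, set_size K, universe_N, p,
#'   fdr) sorted by p.
#' @export
hypergeom_enrich <- function(targets, collection, universe = NULL,
                             min_size = 2L, max_size = 500L) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  if (is.null(universe)) universe <- unique(unlist(collection))
  targets <- unique(targets)
  outside <- setdiff(targets, universe)
  if (length(outside)) {
    warning(length(outside), " target gene(s) outside the universe dropped")
    targets <- intersect(targets, universe)
  }
  N <- length(universe)
  n <- length(targets)
  sets <- lapply(collection, intersect, universe)
  K <- lengths(sets)
  keep <- K >= min_size & K <= max_size
  sets <- sets[keep]; K <- K[keep]
  k <- vapply(sets, function(s) length(intersect(targets, s)), integer(1L))
  # P(X >= k), X ~ Hypergeometric(N, K, n)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set = names(sets), k = k, n_targets = n, set_size = K,
                    universe_N = N, p = p,
                    fdr = p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Yin/Yang targets of one regulator
#'
#' The genes with a nonzero binding-site count for the regulator, intersected
#' with the identified Yin and Yang genes.
#'
#' @param regulator regulator (column) id.
#' @param binding genes x regulators binding matrix (TF or miRNA).
#' @param yin_yang character vector of Yin and Yang gene ids.
#' @return character vector of target genes.
#' @export
regulator_targets <- function(regulator, binding, yin_yang) {
  if (!regulator %in% colnames(binding))
    stop("unknown regulator: ", regulator)
  hit <- rownames(binding)[binding[, regulator] > 0]
  intersect(hit, yin_yang)
}

#' Regulator-target network edge table
#'
#' Compiles the (regulator, target gene, binding hits) triples for the
#' selected regulators, keeping pairs with nonzero hits whose target belongs
#' to at least one of the supplied pathway gene sets (and, when provided, to
#' the Yin/Yang genes). Rows are ordered deterministically by regulator then
#' target. The table is importable into Cytoscape directly or via
#' [write_sif()].
#'
#' @param regulators character vector of selected TF/miRNA ids.
#' @param tf_binding,mirna_binding genes x regulator binding matrices; each
#'   regulator is looked up in whichever matrix carries it.
#' @param pathway_sets named list of pathway gene sets used as the filter.
#' @param yin_yang optional Yin/Yang restriction on targets (default: none).
#' @return data frame (regulator, target, hits), hits > 0 in every row.
#' @export
build_network_table <- function(regulators, tf_binding, mirna_binding,
                                pathway_sets, yin_yang = NULL) {
  pathway_genes <- unique(unlist(pathway_sets))
  rows <- lapply(sort(regulators), function(r) {
    binding <- if (r %in% colnames(tf_binding)) tf_binding
      else if (r %in% colnames(mirna_binding)) mirna_binding
      else stop("unknown regulator: ", r)
    hits <- binding[, r]
    keep <- hits > 0 & rownames(binding) %in% pathway_genes
    if (!is.null(yin_yang)) keep <- keep & rownames(binding) %in% yin_yang
    g <- rownames(binding)[keep]
    if (!length(g)) return(NULL)
    ord <- order(g)
    data.frame(regulator = r, target = g[ord], hits = hits[keep][ord],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(regulator = character(), target = character(),
                      hits = numeric(), stringsAsFactors = FALSE)
  out
}
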