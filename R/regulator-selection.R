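#' Leave-regulator-out loss increase per subtype
#'
#' For every TF/miRNA regulator and every subtype, computes the increase in
#' total squared prediction loss, summed over the subtype's tumors and all
#' modelled genes, when that regulator's fitted coefficient is set to zero in
#' every model of the subtype — without refitting. Regulators whose
#' coefficient is zero in every model of a subtype score exactly 0 there.
#'
#' @param model_set a [fit_all_tumors()] result.
#' @param dataset the [omics_dataset()] the models were fitted on.
#' @return regulators x subtypes matrix of loss increases.
#' @export
score_all_regulators <- function(model_set, dataset) {
  stopifnot(inherits(model_set, "tumor_model_set"))
  inputs <- prepare_model_inputs(dataset, model_set$genes,
                                 model_set$mirna_threshold)
  tumors <- inputs$tumors
  regs <- c(colnames(inputs$tf), colnames(inputs$mir))
  subtypes <- sort(unique(as.character(model_set$subtype)))
  scores <- matrix(0, length(regs), length(subtypes),
                   dimnames = list(regs, subtypes))
  Xbind <- cbind(inputs$tf, inputs$mir)  # genes x regulators, shared
  for (k in tumors) {
    w <- model_set$model_matrix[k, ]
    pred <- model_set$intercepts[[k]] +
      inputs$cnv[, k] * w[["CNV"]] + inputs$meth[, k] * w[["DM"]] +
      as.numeric(Xbind %*% w[regs])
    resid <- inputs$y[, k] - pred
    inc <- .loo_loss_increments(Xbind, resid, w[regs])
    s <- as.character(model_set$subtype[[k]])
    scores[, s] <- scores[, s] + inc
  }
  scores
}

#' @rdname score_all_regulators
#' @param regulator a single TF or miRNA id.
#' @param subtype optional subtype label; when omitted, the regulator's score
#'   in every subtype is returned.
#' @export
score_regulator <- function(model_set, dataset, regulator, subtype = NULL) {
  scores <- score_all_regulators(model_set, dataset)
  if (!regulator %in% rownames(scores))
    stop("unknown regulator: ", regulator)
  if (is.null(subtype)) return(scores[regulator, ])
  if (!subtype %in% colnames(scores)) stop("unknown subtype: ", subtype)
  scores[regulator, subtype]
}

#' Permute a binding matrix over genes
#'
#' Each regulator column's entries are permuted across genes with an
#' independent draw per column, preserving every column's multiset of counts
#' (and hence its marginal distribution) while destroying gene-regulator
#' associations.
#'
#' @param binding genes x regulators matrix.
#' @param seed integer seed.
#' @return permuted matrix with the original dimnames.
#' @export
permute_binding <- function(binding, seed) {
  with_seed(seed, {
    out <- binding
    for (j in seq_len(ncol(binding)))
      out[, j] <- binding[sample.int(nrow(binding)), j]
    out
  })
}

#' Permutation null distribution of regulator scores
#'
#' One randomization permutes every TF and miRNA binding column over genes
#' independently, retrains every tumor's lasso model on the randomized
#' design, and recomputes the leave-regulator-out score of every regulator in
#' every subtype. By default each tumor's penalty from the observed fit is
#' reused (column permutation preserves the scale statistics the penalty
#' depends on); `retune_lambda = TRUE` re-runs the full CV per permutation.
#' Each permutation draws from its own seed substream, so results are
#' identical for any worker count.
#'
#' @inheritParams score_all_regulators
#' @param n_permutations number of randomizations (>= 1). 200 is adequate for
#'   testing; 5000 for full runs.
#' @param seed master seed fanned out to per-permutation substreams.
#' @param retune_lambda re-select each tumor's penalty by CV within every
#'   permutation (default FALSE: reuse the observed penalty).
#' @param n_workers forked workers for the permutation loop (default 1).
#' @return array `(n_permutations, regulators, subtypes)` of null scores.
#' @export
null_distribution <- function(model_set, dataset, n_permutations = 200L,
                              seed = 1, retune_lambda = FALSE, n_workers = 1L) {
  stopifnot(inherits(model_set, "tumor_model_set"))
  if (n_permutations < 1L) stop("n_permutations must be >= 1 (no null otherwise)")
  inputs <- prepare_model_inputs(dataset, model_set$genes,
                                 model_set$mirna_threshold)
  tumors <- inputs$tumors
  G <- length(inputs$genes)
  nT <- ncol(inputs$tf); nM <- ncol(inputs$mir)
  regs <- c(colnames(inputs$tf), colnames(inputs$mir))
  subtypes <- sort(unique(as.character(model_set$subtype)))
  sub_of <- as.character(model_set$subtype[tumors])

  # standardise once: column permutation leaves means/sds unchanged
  std <- function(m) {
    ctr <- colMeans(m)
    z <- sweep(m, 2L, ctr, `-`)
    scl <- sqrt(colMeans(z^2))
    ok <- scl > 0
    z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, scl[ok], `/`)
    z[, !ok] <- 0
    list(z = z, ok = ok)
  }
  ztf <- std(inputs$tf); zmir <- std(inputs$mir)
  zc <- std(inputs$cnv); zd <- std(inputs$meth)
  yc <- sweep(inputs$y, 2L, colMeans(inputs$y), `-`)
  adm <- inputs$admitted
  lam <- model_set$lambda
  n_folds <- model_set$n_folds

  perm_seeds <- derive_seeds(seed, n_permutations)

  one_perm <- function(b) {
    pz <- with_seed(perm_seeds[b], {
      idx_tf <- replicate(nT, sample.int(G))
      idx_mir <- replicate(nM, sample.int(G))
      list(tf = ztf$z[cbind(as.vector(idx_tf), rep(seq_len(nT), each = G))],
           mir = zmir$z[cbind(as.vector(idx_mir), rep(seq_len(nM), each = G))],
           cv_seed = sample.int(2L^30L, 1L))
    })
    ptf <- matrix(pz$tf, G, nT)
    pmir <- matrix(pz$mir, G, nM)
    out <- matrix(0, length(regs), length(subtypes),
                  dimnames = list(regs, subtypes))
    xvar_tf <- as.numeric(ztf$ok); xvar_mir <- as.numeric(zmir$ok)
    for (i in seq_along(tumors)) {
      k <- tumors[i]
      a <- adm[[k]]
      X <- cbind(zc$z[, i], zd$z[, i], ptf, pmir[, a, drop = FALSE])
      xvar <- c(as.numeric(zc$ok[i]), as.numeric(zd$ok[i]),
                xvar_tf, xvar_mir[a])
      lam_k <- if (retune_lambda) {
        cvfit <- cv_lasso(X, yc[, i], n_folds = n_folds,
                          seed = pz$cv_seed + i, intercept = FALSE)
        cvfit$lambda
      } else lam[[k]]
      bstd <- .cd_lasso_path(X, yc[, i], lam_k, xvar, 1e-7, 100000L)[, 1L]
      resid <- yc[, i] - as.numeric(X %*% bstd)
      nreg <- 2L + nT + length(a)
      inc <- .loo_loss_increments(X[, 3:nreg, drop = FALSE], resid,
                                  bstd[3:nreg])
      s <- sub_of[i]
      out[seq_len(nT), s] <- out[seq_len(nT), s] + inc[seq_len(nT)]
      if (length(a))
        out[nT + a, s] <- out[nT + a, s] + inc[nT + seq_along(a)]
    }
    out
  }

  res <- if (n_workers > 1L) {
    parallel::mclapply(seq_len(n_permutations), one_perm,
                       mc.cores = n_workers, mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n_permutations), one_perm)
  }
  nulls <- array(NA_real_, dim = c(n_permutations, length(regs), length(subtypes)),
                 dimnames = list(NULL, regs, subtypes))
  for (b in seq_len(n_permutations)) nulls[b, , ] <- res[[b]]
  nulls
}

#' Empirical p-values and BH selection of key regulators
#'
#' The empirical p-value of a regulator in a subtype is
#' `(1 + #permutations with null score >= observed) / (1 + n_permutations)`.
#' Benjamini-Hochberg adjustment is applied within each subtype across the
#' combined TF + miRNA regulator list; regulators with FDR below `fdr_cut`
#' are selected.
#'
#' @param observed regulators x subtypes score matrix from
#'   [score_all_regulators()].
#' @param nulls null score array from [null_distribution()].
#' @param fdr_cut selection threshold on the BH-adjusted p-value (default
#'   0.05, strict `<`).
#' @return data frame (regulator, subtype, score, p, fdr, selected); the
#'   per-subtype selected sets are in the `"selected_sets"` attribute.
#' @export
empirical_fdr <- function(observed, nulls, fdr_cut = 0.05) {
  stopifnot(length(dim(nulls)) == 3L,
            identical(rownames(observed), dimnames(nulls)[[2L]]),
            identical(colnames(observed), dimnames(nulls)[[3L]]))
  n_perm <- dim(nulls)[1L]
  regs <- rownames(observed); subtypes <- colnames(observed)
  res <- do.call(rbind, lapply(subtypes, function(s) {
    p <- vapply(seq_along(regs), function(r) {
      (1 + sum(nulls[, r, s] >= observed[r, s])) / (1 + n_perm)
    }, numeric(1L))
    data.frame(regulator = regs, subtype = s, score = observed[, s],
               p = p, fdr = p.adjust(p, method = "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  res$selected <- res$fdr < fdr_cut
  sets <- lapply(split(res, res$subtype),
                 function(d) d$regulator[d$selected])
  attr(res, "selected_sets") <- sets[subtypes]
  res
}

#' Cross-classify selected regulators by subtype combination
#'
#' Assigns every selected regulator to exactly one row: the exact combination
#' of subtypes that selected it (regulators selected by all subtypes are the
#' common regulators; singleton rows are subtype-specific).
#'
#' @param selected_sets named list (one character vector of regulators per
#'   subtype).
#' @return data frame (subtypes, n_regulators, regulators), ordered by
#'   decreasing combination size; the underlying list of groups is in the
#'   `"groups"` attribute.
#' @export
classify_shared <- function(selected_sets) {
  stopifnot(is.list(selected_sets), !is.null(names(selected_sets)))
  subtype_names <- names(selected_sets)
  all_regs <- sort(unique(unlist(selected_sets)))
  if (length(all_regs) == 0L) {
    out <- data.frame(subtypes = character(), n_regulators = integer(),
                      regulators = character(), stringsAsFactors = FALSE)
    attr(out, "groups") <- list()
    return(out)
  }
  combo <- vapply(all_regs, function(r) {
    paste(subtype_names[vapply(selected_sets, function(s) r %in% s, logical(1L))],
          collapse = ",")
  }, character(1L))
  groups <- split(all_regs, combo)
  sizes <- lengths(strsplit(names(groups), ",", fixed = TRUE))
  ord <- order(-sizes, names(groups))
  groups <- groups[ord]
  out <- data.frame(
    subtypes = names(groups),
    n_regulators = lengths(groups),
    regulators = vapply(groups, paste, character(1L), collapse = ", "),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "groups") <- groups
  out
}

#' Full regulator-selection pipeline
#'
#' Fits all per-tumor models, scores every regulator per subtype, builds the
#' permutation null, applies empirical-p / BH selection and cross-classifies
#' the selected regulators by subtype combination.
#'
#' @inheritParams fit_all_tumors
#' @inheritParams null_distribution
#' @inheritParams empirical_fdr
#' @return list with `model_set`, `scores`, `nulls`, `result` (the
#'   [empirical_fdr()] table), `selected_sets` and `shared` (the
#'   [classify_shared()] table).
#' @export
select_regulators <- function(dataset, genes = NULL, mirna_threshold = 0,
                              n_folds = 10L, n_permutations = 200L, seed = 1,
                              fdr_cut = 0.05, retune_lambda = FALSE,
                              n_workers = 1L) {
  seeds <- derive_seeds(seed, 2L)
  model_set <- fit_all_tumors(dataset, genes = genes,
                              mirna_threshold = mirna_threshold,
                              n_folds = n_folds, seed = seeds[1L])
  scores <- score_all_regulators(model_set, dataset)
  nulls <- null_distribution(model_set, dataset,
                             n_permutations = n_permutations, seed = seeds[2L],
                             retune_lambda = retune_lambda,
                             n_workers = n_workers)
  result <- empirical_fdr(scores, nulls, fdr_cut = fdr_cut)
  sets <- attr(result, "selected_sets")
  list(model_set = model_set, scores = scores, nulls = nulls, result = result,
       selected_sets = sets, shared = classify_shared(sets))
}
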