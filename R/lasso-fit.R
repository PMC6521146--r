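#' Lasso solutions along a penalty path
#'
#' Solves `min (1/2n) ||y - b0 - X b||^2 + lambda * sum_j |b_j|` by pathwise
#' coordinate descent with warm starts over a decreasing `lambda` grid.
#' Features are standardised internally (zero mean, unit 1/n-variance) so the
#' penalty is comparable across count-scaled and beta-scaled columns;
#' coefficients are reported on the original scale. Constant columns get a
#' zero coefficient. With `intercept = FALSE` columns are scaled but not
#' centred and no intercept is fitted.
#'
#' @param X design matrix (rows = genes, columns = features).
#' @param y response vector.
#' @param lambda decreasing vector of penalty values; defaults to
#'   [lambda_grid()] of the data.
#' @param intercept fit an unpenalised intercept (default TRUE).
#' @param standardize standardise columns internally (default TRUE).
#' @param tol coordinate-descent convergence tolerance (max coefficient
#'   update, standardised scale).
#' @param maxit maximum coordinate-descent sweeps per penalty value.
#' @return list with `beta` (p x L coefficients, original scale), `a0`
#'   (intercepts), `lambda`, and `beta_std` (standardised-scale coefficients).
#' @export
fit_lasso_path <- function(X, y, lambda = NULL, intercept = TRUE,
                           standardize = TRUE, tol = 1e-9, maxit = 100000L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  n <- nrow(X); p <- ncol(X)

  ctr <- if (intercept) colMeans(X) else rep(0, p)
  Z <- sweep(X, 2L, ctr, `-`)
  scl <- sqrt(colMeans(Z^2))
  ok <- scl > 0
  scl[!ok] <- 1
  Z <- sweep(Z, 2L, scl, `/`)
  Z[, !ok] <- 0
  xvar <- ifelse(ok, colMeans(Z^2), 0)
  if (!standardize) {
    Z <- sweep(X, 2L, ctr, `-`)
    scl <- rep(1, p)
    xvar <- colMeans(Z^2)
  }
  ybar <- if (intercept) mean(y) else 0
  yc <- y - ybar

  if (is.null(lambda)) lambda <- lambda_grid(Z, yc, standardized = TRUE)
  lambda <- sort(lambda, decreasing = TRUE)

  bstd <- .cd_lasso_path(Z, yc, lambda, xvar, tol, as.integer(maxit))
  beta <- bstd / scl
  a0 <- ybar - as.numeric(crossprod(ctr, beta))
  dimnames(beta) <- list(colnames(X), NULL)
  dimnames(bstd) <- list(colnames(X), NULL)
  list(beta = beta, a0 = a0, lambda = lambda, beta_std = bstd,
       center = ctr, scale = scl, ybar = ybar)
}

#' Default penalty grid
#'
#' 100 log-spaced penalty values from `lambda_max` (the smallest penalty at
#' which every coefficient is zero) down four decades, following the usual
#' pathwise-fitting convention.
#'
#' @param X design matrix (standardised internally unless
#'   `standardized = TRUE`).
#' @param y response (centred internally unless `standardized = TRUE`).
#' @param nlambda number of grid points (default 100).
#' @param decades how many decades below `lambda_max` the grid extends.
#' @param standardized set when `X` / `y` are already standardised/centred.
#' @return decreasing numeric vector of penalties.
#' @export
lambda_grid <- function(X, y, nlambda = 100L, decades = 4, standardized = FALSE) {
  X <- as.matrix(X)
  if (!standardized) {
    ctr <- colMeans(X)
    Z <- sweep(X, 2L, ctr, `-`)
    scl <- sqrt(colMeans(Z^2)); scl[scl == 0] <- 1
    Z <- sweep(Z, 2L, scl, `/`)
    yc <- y - mean(y)
  } else {
    Z <- X; yc <- y
  }
  lmax <- max(abs(crossprod(Z, yc)) / nrow(Z))
  if (lmax <= 0) lmax <- 1e-3
  10^seq(log10(lmax), log10(lmax) - decades, length.out = nlambda)
}

#' Cross-validated lasso over a shared penalty grid
#'
#' K-fold cross-validation by seeded shuffle of the row (gene) indices. Each
#' fold's model path is fitted on the training rows only; predictions on the
#' held-out rows give the per-fold squared error across the grid and, at the
#' selected penalty, the held-out Spearman rank correlation between predicted
#' and observed responses. The selected penalty minimises the mean CV error.
#'
#' @inheritParams fit_lasso_path
#' @param n_folds number of folds (default 10).
#' @param seed seed for the fold shuffle (ignored when `foldid` is given).
#' @param foldid optional integer fold assignment of length `nrow(X)`,
#'   allowing identical folds across compared feature subsets.
#' @return list with `lambda` (selected), `lambda_idx`, `cv_mse` (grid),
#'   `cv_spearman` (mean held-out Spearman at the selected penalty),
#'   `foldid`, and `lambda_path` (the grid).
#' @export
cv_lasso <- function(X, y, n_folds = 10L, lambda = NULL, seed = 1,
                     foldid = NULL, intercept = TRUE, tol = 1e-7,
                     maxit = 100000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_folds) stop("fewer rows (genes) than folds")
  if (is.null(foldid))
    foldid <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  stopifnot(length(foldid) == n)
  if (is.null(lambda)) lambda <- lambda_grid(X, y)
  lambda <- sort(lambda, decreasing = TRUE)
  L <- length(lambda)

  folds <- sort(unique(foldid))
  mse <- matrix(NA_real_, length(folds), L)
  pred_test <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test <- foldid == folds[f]
    fit <- fit_lasso_path(X[!test, , drop = FALSE], y[!test], lambda = lambda,
                          intercept = intercept, tol = tol, maxit = maxit)
    ph <- X[test, , drop = FALSE] %*% fit$beta
    ph <- sweep(ph, 2L, fit$a0, `+`)
    mse[f, ] <- colMeans((y[test] - ph)^2)
    pred_test[[f]] <- ph
  }
  cvm <- colMeans(mse)
  idx <- which.min(cvm)
  sp <- vapply(seq_along(folds), function(f) {
    test <- foldid == folds[f]
    suppressWarnings(cor(pred_test[[f]][, idx], y[test], method = "spearman"))
  }, numeric(1L))
  sp[is.na(sp)] <- 0  # degenerate fold (constant predictions)
  list(lambda = lambda[idx], lambda_idx = idx, cv_mse = cvm,
       cv_spearman = mean(sp), foldid = foldid, lambda_path = lambda)
}

#' Fit one tumor's lasso model
#'
#' Selects the penalty by K-fold cross-validation over the genes (CV-minimum
#' rule), then refits on all genes at the selected penalty. The returned
#' model carries the coefficient vector on the original feature scale, the
#' intercept, the chosen penalty and the mean held-out Spearman correlation.
#'
#' @param X design matrix from [build_design()] (genes x features).
#' @param y the tumor's fold-change response over the same genes.
#' @param n_folds number of CV folds (default 10).
#' @param lambda optional penalty grid (default [lambda_grid()]).
#' @param seed fold-shuffle seed.
#' @param intercept fit an unpenalised intercept (default TRUE; the response
#'   is a fold change with nonzero mean).
#' @param foldid optional explicit fold assignment.
#' @return object of class `tumor_model`: `coefficients` (named),
#'   `intercept`, `lambda`, `cv_spearman`, `cv_mse`, `lambda_path`.
#' @export
fit_tumor_lasso <- function(X, y, n_folds = 10L, lambda = NULL, seed = 1,
                            intercept = TRUE, foldid = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < n_folds) stop("fewer genes than folds")
  cv <- cv_lasso(X, y, n_folds = n_folds, lambda = lambda, seed = seed,
                 foldid = foldid, intercept = intercept)
  # warm-started refit on the full gene set, path truncated at the chosen
  # penalty
  path <- cv$lambda_path[seq_len(cv$lambda_idx)]
  fit <- fit_lasso_path(X, y, lambda = path, intercept = intercept)
  k <- length(path)
  structure(list(
    coefficients = setNames(fit$beta[, k], colnames(X)),
    intercept = fit$a0[k],
    lambda = cv$lambda,
    cv_spearman = cv$cv_spearman,
    cv_mse = min(cv$cv_mse),
    lambda_path = cv$lambda_path
  ), class = "tumor_model")
}

#' @export
print.tumor_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("tumor lasso model: lambda =", signif(x$lambda, 4),
      "|", nz, "of", length(x$coefficients), "nonzero coefficients",
      "| CV Spearman =", signif(x$cv_spearman, 3), "\n")
  invisible(x)
}

#' @export
predict.tumor_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(object$intercept + newdata %*% object$coefficients)
}

#' Karush-Kuhn-Tucker residual of a lasso solution
#'
#' On the standardised problem, a lasso solution must satisfy
#' `|g_j| <= lambda` for zero coefficients and `g_j = lambda * sign(b_j)` for
#' nonzero ones, where `g_j = (1/n) z_j' r` is the gradient of the smooth
#' part. Returns the largest violation across features — a correctness probe
#' for the solver.
#'
#' @param X,y the data passed to the fit.
#' @param beta_std standardised-scale coefficients (one column of
#'   `fit_lasso_path()$beta_std`).
#' @param lambda the penalty of that solution.
#' @param intercept whether the fit included an intercept.
#' @return maximum KKT violation (nonnegative scalar).
#' @export
lasso_kkt_check <- function(X, y, beta_std, lambda, intercept = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  ctr <- if (intercept) colMeans(X) else rep(0, ncol(X))
  Z <- sweep(X, 2L, ctr, `-`)
  scl <- sqrt(colMeans(Z^2))
  ok <- scl > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2L, scl[ok], `/`)
  Z[, !ok] <- 0
  yc <- if (intercept) y - mean(y) else y
  r <- yc - Z %*% beta_std
  g <- as.numeric(crossprod(Z, r)) / n
  viol <- ifelse(beta_std == 0, pmax(abs(g) - lambda, 0),
                 abs(g - lambda * sign(beta_std)))
  max(viol[ok], 0)
}
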