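# Independent brute-force oracles used across the test files. These are
# deliberately naive (loops, enumeration, closed forms) and share no code
# with the package implementation.

# Benjamini-Hochberg step-up, textbook formulation
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric P(X >= k) by explicit PMF summation
hyper_tail_oracle <- function(N, K, n, k) {
  if (k <= 0) return(1)
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Exact Wilcoxon signed-rank p by enumeration of all 2^n sign patterns
# (assumes no zero and no tied |d|)
signed_rank_p_oracle <- function(d, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  if (alternative == "greater") {
    mean(v_all >= v_obs)
  } else {
    mu <- n * (n + 1) / 4
    mean(abs(v_all - mu) >= abs(v_obs - mu))
  }
}

# Kaplan-Meier product-limit by explicit risk-set bookkeeping
km_oracle <- function(time, event) {
  times <- sort(unique(time))
  s <- 1
  out <- data.frame(time = times, surv = NA_real_)
  for (i in seq_along(times)) {
    at_risk <- sum(time >= times[i])
    d <- sum(time == times[i] & event == 1)
    if (at_risk > 0) s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# Two-group log-rank statistic by explicit O-E / variance summation
logrank_oracle <- function(time, event, group) {
  group <- as.factor(group)
  g1 <- levels(group)[1L]
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Naive leave-regulator-out loss increase: rebuild every design, zero one
# coefficient, recompute both losses with explicit loops
naive_regulator_score <- function(model_set, dataset, regulator, subtype) {
  genes <- model_set$genes
  tumors <- names(model_set$subtype)[model_set$subtype == subtype]
  W <- model_set$model_matrix
  total <- 0
  for (k in tumors) {
    X <- build_design(dataset, k, genes = genes,
                      mirna_threshold = model_set$mirna_threshold)
    y <- tumor_fold_changes(dataset$expr_tumor, dataset$expr_normal, genes)[, k]
    w <- W[k, colnames(X)]
    w0 <- w
    if (regulator %in% names(w0)) w0[regulator] <- 0
    for (g in seq_along(y)) {
      pred_full <- model_set$intercepts[[k]] + sum(X[g, ] * w)
      pred_drop <- model_set$intercepts[[k]] + sum(X[g, ] * w0)
      total <- total + unname((y[g] - pred_drop)^2 - (y[g] - pred_full)^2)
    }
  }
  total
}

# A small, quick synthetic dataset for structural tests
small_sim <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_tumors_per_subtype = 3, n_normals = 6, n_genes = 60,
                   n_tfs = 4, n_mirnas = 5, n_active_per_subtype = 2,
                   n_yin = 5, n_yang = 5, seed = seed)
  defaults[names(args)] <- args
  generate_dataset(do.call(sim_config, defaults))
}
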