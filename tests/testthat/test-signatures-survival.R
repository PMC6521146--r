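test_that("YMR is the per-patient ratio of Yin to Yang means", {
  expr <- rbind(
    matrix(4, 2, 3, dimnames = list(c("y1", "y2"), paste0("p", 1:3))),
    matrix(2, 3, 3, dimnames = list(c("z1", "z2", "z3"), paste0("p", 1:3)))
  )
  s <- ymr_score(expr, yin = c("y1", "y2"), yang = c("z1", "z2", "z3"))
  expect_equal(unname(s), rep(2, 3))
  s2 <- ymr_score(expr, yin = c("y1", "y2"), yang = c("y1", "y2"))
  expect_equal(unname(s2), rep(1, 3))
  expr["z1", "p2"] <- -7   # yang mean <= 0 for p2
  expect_error(ymr_score(expr, c("y1", "y2"), c("z1", "z2", "z3")), "p2")
})

test_that("YMR matches a per-patient loop", {
  set.seed(31)
  expr <- matrix(runif(80, 1, 10), 8, 10,
                 dimnames = list(paste0("g", 1:8), paste0("p", 1:10)))
  yin <- paste0("g", 1:3); yang <- paste0("g", 4:8)
  s <- ymr_score(expr, yin, yang)
  for (p in colnames(expr))
    expect_equal(s[[p]], mean(expr[yin, p]) / mean(expr[yang, p]))
})

test_that("mean-cutoff stratification puts ties in the low-risk group", {
  g <- stratify_by_mean(c(a = 1, b = 3))
  expect_equal(as.character(g), c("Low", "High"))
  expect_warning(g2 <- stratify_by_mean(c(2, 2, 2)), "degenerate")
  expect_true(all(g2 == "Low"))
  set.seed(32)
  sc <- rnorm(50)
  g3 <- stratify_by_mean(sc)
  expect_equal(as.character(g3), ifelse(sc > mean(sc), "High", "Low"))
})

test_that("quantile stratification reproduces the 65/35 split", {
  set.seed(33)
  sc <- sample(seq(0.01, 1, 0.01))   # 100 distinct scores
  g <- xtile_binarize(sc, 0.65)
  expect_equal(sum(g == "Low"), 65L)
  expect_equal(sum(g == "High"), 35L)
  g2 <- xtile_binarize(c(1, 2, 3, 4), 0.5)
  expect_equal(as.character(g2), c("Low", "Low", "High", "High"))
  expect_equal(attr(g2, "cutoff"), 2.5)
  # ties straddling the cutoff fall Low (strict >)
  g3 <- xtile_binarize(c(1, 1, 1, 1, 5), 0.65)
  expect_equal(as.character(g3), c("Low", "Low", "Low", "Low", "High"))
})

test_that("the Cox coefficient is null-consistent and recovers a known hazard ratio", {
  set.seed(34)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = 0.2 * 2^x)   # true hazard ratio 2
  surv <- data.frame(id = paste0("p", 1:n), time = t_event, event = 1L)
  fit <- univariate_cox(x, surv)
  expect_equal(fit$coef, log(2), tolerance = 0.1)
  # independent covariate -> coefficient near zero
  x0 <- rnorm(n)
  surv0 <- data.frame(id = paste0("p", 1:n), time = rexp(n, 0.2), event = 1L)
  expect_lt(abs(univariate_cox(x0, surv0)$coef), 0.1)
  expect_error(univariate_cox(x, transform(surv, event = 0L)), "2 events")
})

test_that("the Cox fit maximises the partial likelihood on a toy table", {
  surv <- data.frame(id = paste0("p", 1:5),
                     time = c(1, 2, 3, 4, 5),
                     event = c(1, 0, 1, 1, 0))
  x <- c(0.5, -1, 2, 0, 1)
  fit <- univariate_cox(x, surv)
  # grid-search the partial log likelihood (no ties -> Breslow = exact)
  pll <- function(b) {
    ll <- 0
    for (i in which(surv$event == 1)) {
      risk <- surv$time >= surv$time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  expect_equal(fit$coef, grid[which.max(vapply(grid, pll, numeric(1)))],
               tolerance = 1e-3)
})

test_that("the combined risk score is the coefficient-weighted expression sum", {
  expr <- matrix(c(1, 2, 3, 4), 2, 2,
                 dimnames = list(c("r1", "r2"), c("p1", "p2")))
  co <- c(r1 = 0.5, r2 = -1)
  s <- crs_score(expr, co)
  expect_equal(unname(s), c(1 * 0.5 - 2, 3 * 0.5 - 4))
  expect_equal(unname(crs_score(expr, c(r1 = 0, r2 = 0))), c(0, 0))
  # invariant to regulator ordering
  expect_equal(crs_score(expr[c("r2", "r1"), ], co), s)
  expect_error(crs_score(expr, c(bad = 1, r1 = 2)), "names")
})

test_that("the product-limit estimate matches hand and textbook computation", {
  # no events: survival stays at 1
  s0 <- km_estimate(data.frame(id = 1:3, time = c(1, 2, 3), event = 0L),
                    rep("A", 3))
  expect_true(all(s0$surv == 1))
  # two patients, events at t = 1 and 2: S = 0.5 on [1,2), 0 after
  s1 <- km_estimate(data.frame(id = 1:2, time = c(1, 2), event = 1L),
                    rep("A", 2))
  expect_equal(s1$surv, c(0.5, 0))
  # random tables vs risk-set recomputation
  set.seed(35)
  for (i in 1:10) {
    n <- 30
    surv <- data.frame(id = seq_len(n), time = round(rexp(n, 0.3), 3),
                       event = rbinom(n, 1, 0.7))
    km <- km_estimate(surv, rep("A", n))
    oracle <- km_oracle(surv$time, surv$event)
    expect_equal(km$surv, oracle$surv[match(km$time, oracle$time)])
  }
})

test_that("the log-rank test matches hand computation and a permutation null", {
  same <- data.frame(id = 1:6, time = rep(c(1, 2, 3), 2), event = 1L)
  lr0 <- logrank_test(same, rep(c("A", "B"), each = 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  toy <- data.frame(id = 1:4, time = c(1, 2, 3, 4), event = 1L)
  grp <- c("A", "A", "B", "B")
  lr <- logrank_test(toy, grp)
  expect_equal(lr$statistic, logrank_oracle(toy$time, toy$event, grp),
               tolerance = 1e-10)

  set.seed(36)
  n <- 40
  surv <- data.frame(id = seq_len(n), time = rexp(n, 0.2),
                     event = rbinom(n, 1, 0.8))
  grp <- rep(c("A", "B"), each = n / 2)
  lr2 <- logrank_test(surv, grp)
  perm <- replicate(2000, logrank_test(surv, sample(grp))$statistic)
  p_perm <- mean(perm >= lr2$statistic)
  expect_lt(abs(p_perm - lr2$p), 3.3 * sqrt(lr2$p * (1 - lr2$p) / 2000) + 0.02)
  expect_error(logrank_test(surv, rep("A", n)), "two")
})

test_that("administrative censoring truncates follow-up at the horizon", {
  surv <- data.frame(id = 1:3, time = c(2, 5, 8), event = c(1L, 1L, 1L))
  out <- censor_at_horizon(surv, horizon = 5)
  expect_equal(out$time, c(2, 5, 5))
  expect_equal(out$event, c(1L, 1L, 0L))
})

test_that("survival tied to the YMR separates the risk groups", {
  sim <- small_sim(seed = 71, n_tumors_per_subtype = 50)
  ds <- sim$dataset
  ymr <- ymr_score(ds$expr_tumor, sim$truth$yin_genes, sim$truth$yang_genes)
  z <- as.numeric(scale(ymr)); names(z) <- names(ymr)
  surv <- generate_survival(0.8 * z, hazard_scale = 0.1, censor_rate = 0.2,
                            seed = 72)
  res <- evaluate_signature(ymr, surv, cutoff = "mean")
  expect_lt(res$logrank$p, 0.05)
  # the high-risk curve sits below the low-risk curve at the median time
  s_at <- function(g, t) {
    k <- res$km[res$km$group == g & res$km$time <= t, ]
    if (nrow(k)) k$surv[nrow(k)] else 1
  }
  tmid <- median(surv$time)
  expect_lt(s_at("High", tmid), s_at("Low", tmid))
})
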