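test_that("a regulator with all-zero coefficients scores exactly zero", {
  sim <- small_sim(seed = 61)
  ms <- fit_all_tumors(sim$dataset, seed = 1)
  # zeroing a coefficient everywhere leaves predictions unchanged when it is
  # dropped, so the loss increase must be exactly 0
  ms$model_matrix[, "TF001"] <- 0
  sc <- score_all_regulators(ms, sim$dataset)
  expect_true(all(sc["TF001", ] == 0))
  expect_error(score_regulator(ms, sim$dataset, "nonexistent"), "unknown regulator")
})

test_that("the single-gene score reduces to forced arithmetic", {
  # y = 2, full prediction 2, w_r = 1, x_r = 1:
  # zeroing r gives prediction 1, so the loss increase is (2-1)^2 - 0 = 1
  resid <- 0                        # y - full prediction
  inc <- yylasso:::.loo_loss_increments(matrix(1), resid, 1)
  expect_equal(inc[1], 1)
})

test_that("vectorised scores equal the naive double-loop recomputation", {
  sim <- small_sim(seed = 62)
  ms <- fit_all_tumors(sim$dataset, seed = 2)
  sc <- score_all_regulators(ms, sim$dataset)
  set.seed(3)
  regs <- sample(rownames(sc), 4)
  for (r in regs) for (s in colnames(sc)) {
    expect_equal(sc[r, s], naive_regulator_score(ms, sim$dataset, r, s),
                 tolerance = 1e-10)
  }
})

test_that("scores are invariant to gene and tumor ordering", {
  sim <- small_sim(seed = 63)
  ds <- sim$dataset
  ms <- fit_all_tumors(ds, seed = 5)
  sc <- score_all_regulators(ms, ds)
  set.seed(6)
  shuf <- function(m) m[sample(nrow(m)), sample(ncol(m)), drop = FALSE]
  ds2 <- intersect_common(shuf(ds$expr_tumor), shuf(ds$expr_normal),
                          shuf(ds$mirna_tumor), shuf(ds$mirna_normal),
                          shuf(ds$cnv), shuf(ds$methylation),
                          shuf(ds$tf_binding), shuf(ds$mirna_binding),
                          ds$subtype)
  sc2 <- score_all_regulators(ms, ds2)
  expect_equal(sc, sc2, tolerance = 1e-12)
})

test_that("binding permutation preserves column multisets", {
  sim <- small_sim(seed = 64)
  b <- sim$dataset$tf_binding
  pb <- permute_binding(b, seed = 9)
  expect_identical(dimnames(pb), dimnames(b))
  expect_equal(colSums(pb), colSums(b))
  for (j in seq_len(ncol(b)))
    expect_equal(sort(pb[, j]), sort(b[, j]), ignore_attr = TRUE)
  # constant columns are unchanged
  const <- matrix(2, 20, 2, dimnames = list(paste0("g", 1:20), c("a", "b")))
  expect_identical(permute_binding(const, seed = 1), const)
  # different seeds give different permutations
  pb2 <- permute_binding(b, seed = 10)
  expect_false(identical(pb, pb2))
  expect_identical(pb, permute_binding(b, seed = 9))
})

test_that("the permutation null is seeded, reproducible and worker-invariant", {
  sim <- small_sim(seed = 65)
  ms <- fit_all_tumors(sim$dataset, seed = 7)
  n1 <- null_distribution(ms, sim$dataset, n_permutations = 8, seed = 11)
  n2 <- null_distribution(ms, sim$dataset, n_permutations = 8, seed = 11)
  expect_identical(n1, n2)
  n3 <- null_distribution(ms, sim$dataset, n_permutations = 8, seed = 11,
                          n_workers = 2)
  expect_equal(n1, n3, tolerance = 1e-12)
  expect_error(null_distribution(ms, sim$dataset, n_permutations = 0), ">= 1")
})

test_that("re-tuned permutations run and stay nonnegative in spread", {
  sim <- small_sim(seed = 66)
  ms <- fit_all_tumors(sim$dataset, seed = 8)
  nl <- null_distribution(ms, sim$dataset, n_permutations = 3, seed = 12,
                          retune_lambda = TRUE)
  expect_equal(dim(nl)[1], 3L)
  expect_true(all(is.finite(nl)))
})

test_that("empirical p-values use the pseudocount formula and BH per subtype", {
  obs <- matrix(c(10, 5), 2, 1, dimnames = list(c("r1", "r2"), "TN"))
  nulls <- array(0, dim = c(100, 2, 1),
                 dimnames = list(NULL, c("r1", "r2"), "TN"))
  nulls[, 2, 1] <- seq(0.1, 10, length.out = 100)   # r2 sits mid-null
  res <- empirical_fdr(obs, nulls)
  expect_equal(res$p[res$regulator == "r1"], 1 / 101)
  expect_equal(res$p[res$regulator == "r2"], (1 + sum(nulls[, 2, 1] >= 5)) / 101,
               tolerance = 1e-12)
  expect_equal(res$p[res$regulator == "r2"], 0.5, tolerance = 0.05)
})

test_that("BH adjustment matches the step-up oracle", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(p.adjust(p, "BH"), c(0.03, 0.03, 0.03))
  set.seed(13)
  for (i in 1:50) {
    pv <- runif(sample(3:40, 1))
    expect_equal(p.adjust(pv, "BH"), bh_stepup_oracle(pv))
  }
})

test_that("subtype cross-classification partitions the selected union", {
  sets <- list(A = c("x", "y"), B = "x", C = character(), D = character())
  out <- classify_shared(sets)
  groups <- attr(out, "groups")
  expect_identical(groups[["A,B"]], "x")
  expect_identical(groups[["A"]], "y")
  expect_setequal(unlist(groups), c("x", "y"))
  empty <- classify_shared(list(A = character(), B = character(),
                                C = character(), D = character()))
  expect_equal(nrow(empty), 0L)
})

test_that("cross-classification matches a powerset brute force", {
  set.seed(14)
  for (i in 1:20) {
    regs <- paste0("r", 1:12)
    sets <- lapply(setNames(nm = c("LumA", "LumB", "Her2", "TN")),
                   function(s) sample(regs, sample(0:8, 1)))
    out <- classify_shared(sets)
    groups <- attr(out, "groups")
    # brute force: assign each regulator to its exact selecting combination
    for (r in unique(unlist(sets))) {
      combo <- paste(names(sets)[vapply(sets, function(s) r %in% s, logical(1))],
                     collapse = ",")
      expect_true(r %in% groups[[combo]])
    }
    expect_equal(sum(lengths(groups)), length(unique(unlist(sets))))
    # groups are disjoint
    expect_equal(anyDuplicated(unlist(groups)), 0L)
  }
})

test_that("null synthetic data yields observed scores inside the null bulk", {
  sim <- small_sim(seed = 67, effect_size = 0.0001, n_genes = 80)
  ms <- fit_all_tumors(sim$dataset, seed = 15)
  sc <- score_all_regulators(ms, sim$dataset)
  nl <- null_distribution(ms, sim$dataset, n_permutations = 40, seed = 16)
  res <- empirical_fdr(sc, nl)
  # no planted signal: nothing should clear the BH threshold
  expect_equal(sum(res$selected), 0L)
})
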