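test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(binding_density = 0), "binding_density")
  expect_error(sim_config(binding_density = 1.2), "binding_density")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(sim_config(n_active_per_subtype = 100, n_tfs = 3, n_mirnas = 3),
               "n_active_per_subtype")
})

test_that("the same seed reproduces the dataset bit for bit", {
  a <- generate_dataset(sim_config(seed = 7, n_genes = 80, n_tumors_per_subtype = 3,
                                   n_normals = 5, n_tfs = 4, n_mirnas = 5,
                                   n_yin = 5, n_yang = 5))
  b <- generate_dataset(sim_config(seed = 7, n_genes = 80, n_tumors_per_subtype = 3,
                                   n_normals = 5, n_tfs = 4, n_mirnas = 5,
                                   n_yin = 5, n_yang = 5))
  expect_identical(a, b)
  c <- generate_dataset(sim_config(seed = 8, n_genes = 80, n_tumors_per_subtype = 3,
                                   n_normals = 5, n_tfs = 4, n_mirnas = 5,
                                   n_yin = 5, n_yang = 5))
  expect_false(identical(a$dataset$expr_tumor, c$dataset$expr_tumor))
})

test_that("matrix shapes follow the configuration", {
  sim <- generate_dataset(sim_config(n_genes = 300, n_tfs = 20, n_mirnas = 30,
                                     n_tumors_per_subtype = 2, n_normals = 4,
                                     seed = 3, n_yin = 10, n_yang = 10))
  ds <- sim$dataset
  expect_equal(dim(ds$expr_tumor), c(300L, 8L))
  expect_equal(dim(ds$tf_binding), c(300L, 20L))
  expect_equal(dim(ds$mirna_binding), c(300L, 30L))
  expect_equal(dim(ds$mirna_tumor), c(30L, 8L))
  expect_equal(length(ds$subtype), 8L)
  expect_setequal(unique(ds$subtype), c("LumA", "LumB", "Her2", "TN"))
})

test_that("generated values respect their platform ranges", {
  sim <- small_sim(seed = 11)
  ds <- sim$dataset
  expect_true(all(ds$methylation >= 0 & ds$methylation <= 1))
  expect_true(all(ds$cnv %in% -2:2))
  expect_true(all(ds$tf_binding >= 0))
  expect_true(all(ds$tf_binding == round(ds$tf_binding)))
  expect_true(all(ds$tf_binding <= sim$truth$config$max_binding_count))
  dens <- mean(ds$mirna_binding > 0)
  expect_gt(dens, 0.03); expect_lt(dens, 0.25)
})

test_that("with zero noise the response equals the generative predictor", {
  sim <- small_sim(seed = 2, noise_sd = 0)
  y <- tumor_fold_changes(sim$dataset$expr_tumor, sim$dataset$expr_normal)
  expect_equal(y, sim$truth$predictor, tolerance = 1e-12)
})

test_that("planted coefficient structure matches the configuration", {
  sim <- small_sim(seed = 4)
  planted <- sim$truth$planted_coefficients
  expect_equal(rowSums(planted != 0), setNames(rep(2, 4), rownames(planted)))
  expect_true(all(abs(planted[planted != 0]) == sim$truth$config$effect_size))
})

test_that("planted-active miRNAs clear the fold-change admission rule", {
  sim <- small_sim(seed = 6, n_active_per_subtype = 4)
  fc <- tumor_fold_changes(sim$dataset$mirna_tumor, sim$dataset$mirna_normal)
  planted <- sim$truth$planted_coefficients
  for (s in rownames(planted)) {
    act <- intersect(colnames(planted)[planted[s, ] != 0], rownames(fc))
    ks <- names(sim$dataset$subtype)[sim$dataset$subtype == s]
    if (length(act)) expect_true(all(abs(fc[act, ks]) >= 0.5))
  }
})

test_that("noiseless data refit at a vanishing penalty recovers planted coefficients", {
  sim <- small_sim(seed = 13, noise_sd = 0, n_yin = 0, n_yang = 0,
                   n_genes = 120, cnv_weight_sd = 0.01, dm_weight_sd = 0.01)
  ds <- sim$dataset
  k <- colnames(ds$expr_tumor)[1L]
  s <- ds$subtype[[k]]
  X <- build_design(ds, k)
  y <- tumor_fold_changes(ds$expr_tumor, ds$expr_normal)[, k]
  fit <- fit_lasso_path(X, y, lambda = 1e-8)
  w <- setNames(fit$beta[, 1L], colnames(X))
  truth <- sim$truth
  expect_equal(w[["CNV"]], unname(truth$cnv_weights[k]), tolerance = 1e-4)
  expect_equal(w[["DM"]], unname(truth$dm_weights[k]), tolerance = 1e-4)
  regs <- intersect(names(w), colnames(truth$planted_coefficients))
  expect_equal(unname(w[regs]),
               unname(truth$planted_coefficients[s, regs]), tolerance = 1e-4)
})

test_that("survival generation is reproducible and respects censoring", {
  sc <- setNames(rep(0.3, 50), sprintf("p%02d", 1:50))
  a <- generate_survival(sc, censor_rate = 0, seed = 5)
  expect_true(all(a$event == 1L))
  b <- generate_survival(sc, censor_rate = 0.4, seed = 5)
  expect_identical(b, generate_survival(sc, censor_rate = 0.4, seed = 5))
  expect_error(generate_survival(c(1, Inf)), "finite")
  expect_error(generate_survival(sc, hazard_scale = -1), "hazard_scale")
})

test_that("a log-2 score difference doubles the empirical hazard", {
  n <- 5000
  sc <- c(rep(0, n), rep(log(2), n))
  surv <- generate_survival(sc, hazard_scale = 0.2, censor_rate = 0, seed = 9)
  rate <- function(idx) sum(surv$event[idx]) / sum(surv$time[idx])
  hr <- rate(n + 1:n) / rate(1:n)
  expect_equal(hr, 2, tolerance = 0.1)
})

test_that("realised censoring fraction tracks the requested rate", {
  sc <- rnorm(4000)
  surv <- generate_survival(sc, censor_rate = 0.3, seed = 10)
  expect_equal(mean(surv$event == 0), 0.3, tolerance = 0.05)
})

test_that("emitted files round-trip losslessly through the readers", {
  sim <- small_sim(seed = 21)
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir)
  back <- read_dataset(dir)
  expect_equal(back, sim$dataset, tolerance = 0)
  gmt <- file.path(dir, "pathways.gmt")
  write_gmt(sim$truth$pathway_sets, gmt)
  expect_identical(read_gmt(gmt), sim$truth$pathway_sets)
})
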