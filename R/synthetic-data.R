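#' Configuration for the synthetic multi-omics generator
#'
#' Fixes every knob of the generative model: cohort shape (tumors per subtype,
#' normals, genes, TFs, miRNAs), the planted regulatory program (number of
#' active regulators per subtype and their coefficient magnitude), noise, the
#' sparsity and scale of the binding matrices, the planted differential
#' expression (Yin/Yang) structure, and censoring for survival generation.
#'
#' @param n_tumors_per_subtype tumors per subtype label (4 subtypes).
#' @param n_normals number of normal samples.
#' @param n_genes number of genes (G).
#' @param n_tfs number of transcription factors (T).
#' @param n_mirnas number of miRNAs (M).
#' @param n_active_per_subtype planted nonzero regulators per subtype.
#' @param effect_size coefficient magnitude of planted regulators.
#' @param noise_sd standard deviation of the Gaussian noise added to the
#'   fold-change response.
#' @param binding_density probability that a regulator targets a gene.
#' @param max_binding_count upper bound on binding-site counts.
#' @param censor_rate fraction of censored survival observations.
#' @param seed integer master seed.
#' @param n_yin,n_yang number of planted up-/down-regulated genes.
#' @param de_effect magnitude (log2 scale) of the planted Yin/Yang offsets.
#' @param cnv_weight_mean,cnv_weight_sd distribution of per-tumor copy-number
#'   weights.
#' @param dm_weight_mean,dm_weight_sd distribution of per-tumor methylation
#'   weights (negative mean: hypermethylation silences).
#' @param expr_noise_sd per-sample expression noise of the normal samples.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_tumors_per_subtype = 25, n_normals = 30,
                       n_genes = 300, n_tfs = 20, n_mirnas = 30,
                       n_active_per_subtype = 5, effect_size = 1,
                       noise_sd = 0.5, binding_density = 0.1,
                       max_binding_count = 5, censor_rate = 0.3, seed = 1,
                       n_yin = 25, n_yang = 25, de_effect = 2.5,
                       cnv_weight_mean = 0.6, cnv_weight_sd = 0.1,
                       dm_weight_mean = -2, dm_weight_sd = 0.2,
                       expr_noise_sd = 0.5) {
  cfg <- as.list(environment())
  counts <- c("n_tumors_per_subtype", "n_normals", "n_genes", "n_tfs", "n_mirnas",
              "n_active_per_subtype", "max_binding_count")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 || v != round(v))
      stop("invalid configuration field '", f, "': must be an integer >= 1")
  }
  for (f in c("n_yin", "n_yang")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v != round(v))
      stop("invalid configuration field '", f, "': must be an integer >= 0")
  }
  if (!is.numeric(cfg$binding_density) || cfg$binding_density <= 0 || cfg$binding_density > 1)
    stop("invalid configuration field 'binding_density': must lie in (0, 1]")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0)
    stop("invalid configuration field 'noise_sd': must be >= 0")
  if (!is.numeric(cfg$censor_rate) || cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("invalid configuration field 'censor_rate': must lie in [0, 1)")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed))
    stop("invalid configuration field 'seed': must be a finite number")
  if (cfg$n_active_per_subtype > cfg$n_tfs + cfg$n_mirnas)
    stop("invalid configuration field 'n_active_per_subtype': exceeds regulator count")
  if (cfg$n_yin + cfg$n_yang > cfg$n_genes)
    stop("invalid configuration field 'n_yin': n_yin + n_yang exceeds n_genes")
  structure(cfg, class = "sim_config")
}

SUBTYPES <- c("LumA", "LumB", "Her2", "TN")

#' Generate a synthetic multi-omics dataset with planted ground truth
#'
#' Draws binding matrices (sparse nonnegative integer counts), discrete
#' copy-number scores, Beta(2, 2) methylation, per-tumor CNV/methylation
#' weights and a planted set of active TF/miRNA regulators per subtype, then
#' generates each tumor's gene-expression fold-change response as the linear
#' combination of its features under its subtype's coefficients plus Gaussian
#' noise. Planted Yin/Yang genes receive an additional baseline offset of
#' `+/- de_effect`. Expression matrices are constructed so that
#' [tumor_fold_changes()] recovers the generative response exactly (normal
#' sample noise is centred per gene), and planted-active miRNAs are guaranteed
#' a tumor fold change of magnitude >= 0.5 in their subtype so the
#' fold-change admission rule never drops planted signal.
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (an [omics_dataset()]) and `truth`
#'   (planted coefficients, per-tumor CNV/DM weights, Yin/Yang gene sets,
#'   per-gene baseline offsets, the noiseless predictor matrix, and planted
#'   pathway gene sets suitable for [write_gmt()]).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 12L)

  G <- cfg$n_genes; T_ <- cfg$n_tfs; M <- cfg$n_mirnas
  N <- 4L * cfg$n_tumors_per_subtype
  genes <- sprintf("g%04d", seq_len(G))
  tfs <- sprintf("TF%03d", seq_len(T_))
  mirnas <- sprintf("miR%03d", seq_len(M))
  tumors <- sprintf("tumor%03d", seq_len(N))
  normals <- sprintf("normal%03d", seq_len(cfg$n_normals))
  subtype <- setNames(rep(SUBTYPES, each = cfg$n_tumors_per_subtype), tumors)
  regulators <- c(tfs, mirnas)

  draw_binding <- function(nr, nc, rn, cn) {
    hit <- rbinom(nr * nc, 1L, cfg$binding_density)
    cnt <- hit * (1L + rpois(nr * nc, 1))
    matrix(pmin(cnt, cfg$max_binding_count), nr, nc, dimnames = list(rn, cn))
  }
  tf_binding <- with_seed(seeds[1L], draw_binding(G, T_, genes, tfs))
  mirna_binding <- with_seed(seeds[2L], draw_binding(G, M, genes, mirnas))

  cnv <- with_seed(seeds[3L], matrix(
    sample(c(-2, -1, 0, 1, 2), G * N, replace = TRUE,
           prob = c(0.05, 0.2, 0.5, 0.2, 0.05)),
    G, N, dimnames = list(genes, tumors)))
  methylation <- with_seed(seeds[4L], matrix(
    stats::rbeta(G * N, 2, 2), G, N, dimnames = list(genes, tumors)))

  w_cn <- with_seed(seeds[5L], setNames(
    rnorm(N, cfg$cnv_weight_mean, cfg$cnv_weight_sd), tumors))
  w_dm <- with_seed(seeds[5L] + 1L, setNames(
    rnorm(N, cfg$dm_weight_mean, cfg$dm_weight_sd), tumors))

  planted <- with_seed(seeds[6L], {
    coefs <- matrix(0, 4L, T_ + M, dimnames = list(SUBTYPES, regulators))
    for (s in SUBTYPES) {
      idx <- sample.int(T_ + M, cfg$n_active_per_subtype)
      coefs[s, idx] <- cfg$effect_size * sample(c(-1, 1), length(idx), replace = TRUE)
    }
    coefs
  })

  de <- with_seed(seeds[7L], {
    idx <- sample.int(G, cfg$n_yin + cfg$n_yang)
    list(yin = genes[idx[seq_len(cfg$n_yin)]],
         yang = genes[idx[cfg$n_yin + seq_len(cfg$n_yang)]])
  })
  de_offset <- setNames(numeric(G), genes)
  de_offset[de$yin] <- cfg$de_effect
  de_offset[de$yang] <- -cfg$de_effect

  # planted pathway gene sets (the Yin and Yang programs plus two random
  # decoy sets), emitted as a GMT file by write_dataset()
  pathway_sets <- with_seed(seeds[7L] + 1L, {
    sets <- list(PLANTED_YIN_PATHWAY = de$yin, PLANTED_YANG_PATHWAY = de$yang)
    sets$DECOY_PATHWAY_1 <- sort(sample(genes, min(30L, G)))
    sets$DECOY_PATHWAY_2 <- sort(sample(genes, min(30L, G)))
    sets[lengths(sets) > 0L]
  })

  # per-tumor miRNA log2 fold changes; planted-active miRNAs are kept away
  # from the admission boundary (|fc| >= 0.5) within their subtype
  mirna_fc <- with_seed(seeds[8L], matrix(
    rnorm(M * N), M, N, dimnames = list(mirnas, tumors)))
  for (s in SUBTYPES) {
    act <- regulators[planted[s, ] != 0]
    act_mir <- intersect(act, mirnas)
    ks <- tumors[subtype == s]
    if (length(act_mir) && length(ks)) {
      blk <- mirna_fc[act_mir, ks, drop = FALSE]
      sgn <- ifelse(blk >= 0, 1, -1)
      mirna_fc[act_mir, ks] <- sgn * pmax(abs(blk), 0.5)
    }
  }

  # Noiseless linear predictor per tumor (its subtype's coefficients), plus
  # the per-gene Yin/Yang baseline offset
  w_tf_by_subtype <- planted[, tfs, drop = FALSE]
  w_mir_by_subtype <- planted[, mirnas, drop = FALSE]
  predictor <- matrix(0, G, N, dimnames = list(genes, tumors))
  for (s in SUBTYPES) {
    ks <- tumors[subtype == s]
    reg_part <- tf_binding %*% w_tf_by_subtype[s, ] +
      mirna_binding %*% w_mir_by_subtype[s, ]
    predictor[, ks] <- de_offset + as.numeric(reg_part)
  }
  # the methylation contribution is centred (beta - 1/2) so that the planted
  # Yin/Yang offsets, not a global methylation shift, set each gene's mean
  # fold change; the per-tumor intercept absorbs the constant in fitting
  predictor <- predictor +
    sweep(cnv, 2L, w_cn, `*`) + sweep(methylation - 0.5, 2L, w_dm, `*`)

  noise <- with_seed(seeds[9L],
    matrix(rnorm(G * N, 0, cfg$noise_sd), G, N))
  y <- predictor + noise

  baseline <- with_seed(seeds[10L], setNames(runif(G, 9, 12), genes))
  normal_eps <- with_seed(seeds[11L],
    matrix(rnorm(G * cfg$n_normals, 0, cfg$expr_noise_sd), G, cfg$n_normals,
           dimnames = list(genes, normals)))
  normal_eps <- normal_eps - rowMeans(normal_eps)  # exact per-gene baseline
  expr_tumor <- baseline + y
  expr_normal <- baseline + normal_eps

  mirna_baseline <- with_seed(seeds[12L], setNames(runif(M, 4, 8), mirnas))
  mirna_normal_eps <- with_seed(seeds[12L] + 1L,
    matrix(rnorm(M * cfg$n_normals, 0, cfg$expr_noise_sd), M, cfg$n_normals,
           dimnames = list(mirnas, normals)))
  mirna_normal_eps <- mirna_normal_eps - rowMeans(mirna_normal_eps)
  mirna_tumor <- mirna_baseline + mirna_fc
  mirna_normal <- mirna_baseline + mirna_normal_eps

  dataset <- omics_dataset(
    expr_tumor = expr_tumor, expr_normal = expr_normal,
    mirna_tumor = mirna_tumor, mirna_normal = mirna_normal,
    cnv = cnv, methylation = methylation,
    tf_binding = tf_binding, mirna_binding = mirna_binding,
    subtype = subtype
  )
  truth <- structure(list(
    planted_coefficients = planted,
    cnv_weights = w_cn, dm_weights = w_dm,
    yin_genes = de$yin, yang_genes = de$yang,
    de_offset = de_offset, predictor = predictor,
    pathway_sets = pathway_sets, config = cfg
  ), class = "yy_ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Generate censored survival times linked to a risk score
#'
#' Event times are exponential with per-patient rate
#' `hazard_scale * exp(score)`; censoring times are drawn independently (also
#' exponential, with rate chosen so each patient's censoring probability
#' equals `censor_rate`), so the realised censoring fraction matches
#' `censor_rate` in expectation.
#'
#' @param scores named numeric vector of per-patient risk scores (finite).
#' @param hazard_scale positive baseline hazard multiplier.
#' @param censor_rate target fraction of censored observations in \[0, 1).
#' @param seed integer seed.
#' @param endpoint endpoint tag recorded in the table (default "OS").
#' @return survival data frame (id, time, event, endpoint).
#' @export
generate_survival <- function(scores, hazard_scale = 0.1, censor_rate = 0.3,
                              seed = 1, endpoint = "OS") {
  if (any(!is.finite(scores))) stop("risk scores must be finite")
  if (!is.numeric(hazard_scale) || hazard_scale <= 0)
    stop("hazard_scale must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  n <- length(scores)
  ids <- names(scores) %||% sprintf("patient%03d", seq_len(n))
  with_seed(seed, {
    rate <- hazard_scale * exp(scores)
    t_event <- rexp(n, rate)
    if (censor_rate > 0) {
      c_rate <- rate * censor_rate / (1 - censor_rate)
      t_cens <- rexp(n, c_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    data.frame(id = ids, time = time, event = event, endpoint = endpoint,
               stringsAsFactors = FALSE)
  })
}
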