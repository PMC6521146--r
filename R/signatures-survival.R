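#' Yin/Yang mean-ratio (YMR) prognostic score
#'
#' Per patient, the ratio of the mean log2 expression over the Yin genes to
#' the mean over the Yang genes.
#'
#' @param expr gene x patient log2 expression matrix.
#' @param yin,yang nonempty Yin / Yang gene sets (rows of `expr`).
#' @return named per-patient score vector.
#' @export
ymr_score <- function(expr, yin, yang) {
  expr <- as.matrix(expr)
  stopifnot(length(yin) > 0L, length(yang) > 0L)
  missing <- setdiff(c(yin, yang), rownames(expr))
  if (length(missing))
    stop("signature genes absent from expression matrix: ",
         paste(head(missing, 5L), collapse = ", "))
  yin_mean <- colMeans(expr[yin, , drop = FALSE])
  yang_mean <- colMeans(expr[yang, , drop = FALSE])
  bad <- which(yang_mean <= 0)
  if (length(bad))
    stop("nonpositive Yang mean for patient(s): ",
         paste(head(colnames(expr)[bad], 5L), collapse = ", "))
  yin_mean / yang_mean
}

#' Stratify patients by the mean score cutoff
#'
#' High-risk iff the score exceeds the mean of the scores (strictly); ties at
#' the cutoff go to the low-risk group. If all scores are identical the
#' stratification is degenerate: everyone is Low and a warning is raised.
#'
#' @param scores named numeric score vector (>= 2 patients).
#' @return named factor over `c("Low", "High")` with the cutoff in the
#'   `"cutoff"` attribute.
#' @export
stratify_by_mean <- function(scores) {
  stopifnot(length(scores) >= 2L)
  cutoff <- mean(scores)
  if (all(scores == scores[1L]))
    warning("all scores identical: degenerate stratification, everyone Low")
  grp <- factor(ifelse(scores > cutoff, "High", "Low"),
                levels = c("Low", "High"))
  names(grp) <- names(scores)
  attr(grp, "cutoff") <- cutoff
  grp
}

#' Stratify patients at an upper quantile of the score
#'
#' The cutoff is the empirical quantile of the scores at `probability`
#' (linear-interpolation, quantile type 7); patients strictly above the
#' cutoff are High. With 100 distinct scores at the default probability this
#' yields a 65 Low / 35 High split.
#'
#' @param scores named numeric score vector (>= 2 patients).
#' @param probability quantile level of the cutoff (default 0.65).
#' @param type quantile convention passed to [stats::quantile()] (default 7).
#' @return named factor over `c("Low", "High")` with the cutoff attribute.
#' @export
xtile_binarize <- function(scores, probability = 0.65, type = 7L) {
  stopifnot(length(scores) >= 2L, probability > 0, probability < 1)
  cutoff <- unname(quantile(scores, probability, type = type, names = FALSE))
  grp <- factor(ifelse(scores > cutoff, "High", "Low"),
                levels = c("Low", "High"))
  names(grp) <- names(scores)
  attr(grp, "cutoff") <- cutoff
  grp
}

#' Univariate Cox proportional-hazards coefficient
#'
#' Fits `Surv(time, event) ~ x` by partial likelihood with Breslow handling
#' of ties and returns the log hazard ratio.
#'
#' @param x per-patient covariate, aligned with (and named as) the rows of
#'   `survival_table`.
#' @param survival_table data frame with columns id, time, event.
#' @return list with `coef` (log hazard ratio), `se`, `p`.
#' @export
univariate_cox <- function(x, survival_table) {
  validate_survival(survival_table)
  if (length(x) != nrow(survival_table))
    stop("covariate length does not match the survival table")
  if (anyNA(x)) stop("missing covariate values are not allowed")
  if (sum(survival_table$event) < 2L)
    stop("need at least 2 events to fit a Cox model")
  fit <- survival::coxph(
    survival::Surv(survival_table$time, survival_table$event) ~ x,
    ties = "breslow",
    control = survival::coxph.control(eps = 1e-10, iter.max = 100L)
  )
  if (!is.finite(fit$coefficients[[1L]]))
    stop("Cox fit did not converge to a finite coefficient")
  s <- summary(fit)
  list(coef = unname(fit$coefficients[1L]),
       se = unname(s$coefficients[1L, "se(coef)"]),
       p = unname(s$coefficients[1L, "Pr(>|z|)"]))
}

#' Combined risk score (CRS)
#'
#' Per patient, the sum over the chosen regulators of expression times the
#' regulator's univariate Cox coefficient: `sum_i x_i * coef_i`. Invariant to
#' regulator ordering.
#'
#' @param expr regulator x patient expression matrix (rows = the regulators).
#' @param coefs named numeric vector of Cox log-hazard-ratio coefficients;
#'   names must match `rownames(expr)` as sets.
#' @return named per-patient score vector.
#' @export
crs_score <- function(expr, coefs) {
  expr <- as.matrix(expr)
  if (is.null(names(coefs)) || !setequal(names(coefs), rownames(expr)))
    stop("coefficient names do not match the expression regulators")
  coefs <- coefs[rownames(expr)]
  colSums(expr * coefs)
}

#' Kaplan-Meier product-limit estimate per group
#'
#' Product-limit survival estimate within each risk group; censored subjects
#' leave the risk set after their censoring time and S(0) = 1.
#'
#' @param survival_table data frame with columns id, time, event.
#' @param groups per-patient group labels aligned with the table rows.
#' @return data frame (group, time, n_risk, n_event, n_censor, surv) with
#'   one row per distinct observed time per group.
#' @export
km_estimate <- function(survival_table, groups) {
  validate_survival(survival_table)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(survival_table))
  if (any(table(groups) == 0L)) stop("every group must be nonempty")
  fit <- survival::survfit(
    survival::Surv(survival_table$time, survival_table$event) ~ groups
  )
  if (is.null(fit$strata)) {
    grp <- rep(levels(groups)[1L], length(fit$time))
  } else {
    grp <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             surv = fit$surv, row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square statistic `(sum(O - E))^2 / Var` with the
#' p-value from a chi-square distribution on 1 degree of freedom.
#'
#' @inheritParams km_estimate
#' @return list with `statistic` and `p`.
#' @export
logrank_test <- function(survival_table, groups) {
  validate_survival(survival_table)
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == nrow(survival_table))
  if (nlevels(groups) != 2L) stop("log-rank test requires exactly two nonempty groups")
  sd_ <- survival::survdiff(
    survival::Surv(survival_table$time, survival_table$event) ~ groups
  )
  stat <- unname(sd_$chisq)
  list(statistic = stat, p = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Administrative censoring at a follow-up horizon
#'
#' Truncates follow-up at `horizon` years: subjects with longer follow-up are
#' censored at the horizon. Used for fixed-horizon (e.g. five-year) survival
#' analyses.
#'
#' @param survival_table data frame with columns id, time, event.
#' @param horizon follow-up horizon (same units as `time`, typically years).
#' @return the truncated survival table.
#' @export
censor_at_horizon <- function(survival_table, horizon = 5) {
  validate_survival(survival_table)
  over <- survival_table$time > horizon
  survival_table$event[over] <- 0L
  survival_table$time[over] <- horizon
  survival_table
}

#' Evaluate a prognostic signature
#'
#' Stratifies patients by score (mean or upper-quantile cutoff), runs the
#' two-group log-rank test and returns the per-patient assignments together
#' with the Kaplan-Meier summary.
#'
#' @param scores named per-patient score vector ([ymr_score()] or
#'   [crs_score()]).
#' @param survival_table survival data frame (id, time, event); ids must
#'   match the score names.
#' @param cutoff `"mean"` ([stratify_by_mean()]) or `"xtile"`
#'   ([xtile_binarize()]).
#' @param xtile_p quantile level for the xtile cutoff (default 0.65).
#' @param horizon optional administrative-censoring horizon in years.
#' @return list with `groups`, `cutoff`, `logrank` (statistic, p), `km`
#'   (the KM summary table) and `table` (per-patient id, score, group).
#' @export
evaluate_signature <- function(scores, survival_table, cutoff = c("mean", "xtile"),
                               xtile_p = 0.65, horizon = NULL) {
  cutoff <- match.arg(cutoff)
  validate_survival(survival_table)
  if (!setequal(names(scores), survival_table$id))
    stop("score names do not match survival table ids")
  scores <- scores[survival_table$id]
  if (!is.null(horizon)) survival_table <- censor_at_horizon(survival_table, horizon)
  groups <- if (cutoff == "mean") stratify_by_mean(scores)
    else xtile_binarize(scores, probability = xtile_p)
  lr <- logrank_test(survival_table, groups)
  list(groups = groups, cutoff = attr(groups, "cutoff"), logrank = lr,
       km = km_estimate(survival_table, groups),
       table = data.frame(id = survival_table$id, score = unname(scores),
                          group = as.character(groups),
                          stringsAsFactors = FALSE))
}
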