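#' E-value for unmeasured confounding
#'
#' The E-value is the minimum strength of association, on the risk-ratio
#' scale, that an unmeasured confounder would need to have with both the
#' exposure and the outcome to fully explain away an observed association.
#' For the rare outcomes studied here the OR is identified with the RR
#' directly; protective ORs are first inverted so the magnitude
#' RR* >= 1, then
#' \deqn{E = RR^* + \sqrt{RR^* (RR^* - 1)}.}
#' The CI E-value applies the same computation to the confidence bound nearer
#' 1 and is set to 1 when the interval crosses 1.
#'
#' @param or_point Odds ratio point estimate (> 0).
#' @param ci_bound_nearer_1 The CI bound nearer the null (> 0), e.g. the
#'   upper bound for a protective estimate; `NULL` to skip.
#' @return An `evalue_result` with `rr_star`, `evalue_point`, `evalue_ci`,
#'   and one-decimal half-up roundings alongside full precision.
#' @export
#' @examples
#' evalue(0.70, 0.99) # point 2.2, CI 1.1 after rounding
evalue <- function(or_point, ci_bound_nearer_1 = NULL) {
  if (!is.numeric(or_point) || or_point <= 0) stop("or_point must be > 0")
  e_of <- function(r) {
    rs <- if (r < 1) 1 / r else r
    rs + sqrt(rs * (rs - 1))
  }
  ep <- e_of(or_point)
  ec <- if (is.null(ci_bound_nearer_1)) NA_real_ else {
    if (ci_bound_nearer_1 <= 0) stop("CI bound must be > 0")
    crosses <- (or_point < 1 && ci_bound_nearer_1 >= 1) ||
      (or_point > 1 && ci_bound_nearer_1 <= 1) || or_point == 1
    if (crosses) 1 else e_of(ci_bound_nearer_1)
  }
  structure(list(
    input_or = or_point,
    rr_star = if (or_point < 1) 1 / or_point else or_point,
    evalue_point = ep, evalue_ci = ec,
    evalue_point_rounded = round_half_up(ep, 1),
    evalue_ci_rounded = if (is.na(ec)) NA_real_ else round_half_up(ec, 1)
  ), class = "evalue_result")
}

#' @export
print.evalue_result <- function(x, ...) {
  cat(sprintf("<evalue> OR %.3g -> E-value %.1f (point)", x$input_or,
              x$evalue_point_rounded))
  if (!is.na(x$evalue_ci)) cat(sprintf(", %.1f (CI bound)", x$evalue_ci_rounded))
  cat("\n")
  invisible(x)
}

#' Pre-index health trend by exposure arm
#'
#' For each of the `months_back` 30-day windows before the index admission,
#' the proportion of each arm with at least one inpatient admission in that
#' window, with exact (Clopper-Pearson) 95% binomial CIs. Parallel trends
#' between arms indicate that neither group was declining faster before
#' index.
#'
#' @param cohort A `cohort` from [build_cohort()].
#' @param admissions The raw admissions table for the same source (data frame
#'   with `patient_id`, `admit_date`, `discharge_date`).
#' @param months_back Number of 30-day pre-index windows.
#' @return A `health_trend` data frame: `month`, `arm`, `n`, `proportion`,
#'   `lower`, `upper`.
#' @export
health_trend <- function(cohort, admissions, months_back = 12) {
  if (!any(cohort$exposure == 1L) || !any(cohort$exposure == 0L)) {
    stop("both exposure arms must be nonempty")
  }
  adm <- as.data.table(admissions)
  idx <- data.table(patient_id = cohort$patient_id,
                    index_date = cohort$index_date,
                    exposure = cohort$exposure)
  adm <- merge(adm, idx, by = "patient_id")
  adm <- adm[admit_date < index_date]
  cp_ci <- function(x, n) {
    lo <- if (x == 0) 0 else qbeta(0.025, x, n - x + 1)
    hi <- if (x == n) 1 else qbeta(0.975, x + 1, n - x)
    c(lo, hi)
  }
  rows <- list()
  for (m in seq_len(months_back)) {
    hit <- adm[admit_date >= index_date - 30L * m &
                 admit_date < index_date - 30L * (m - 1L), unique(patient_id)]
    for (arm in c(1L, 0L)) {
      ids <- idx[exposure == arm, patient_id]
      n <- length(ids)
      x <- sum(ids %in% hit)
      ci <- cp_ci(x, n)
      rows[[length(rows) + 1L]] <- data.frame(
        month = m, arm = if (arm == 1L) "exposed" else "unexposed",
        n = n, proportion = x / n, lower = ci[1], upper = ci[2])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("health_trend", "data.frame")
  out
}

#' Alternative causal estimators: IPW means and AIPW
#'
#' Robustness companions to the weighted outcome regression:
#' \itemize{
#'   \item Hajek-normalized IPW contrast of outcome means with ATT weights
#'     (exposed weight 1, unexposed e/(1-e)), reported on the risk-difference
#'     and OR scales with influence-function variances.
#'   \item The augmented IPW (AIPW, doubly robust) estimator of the ATE with
#'     cross-fitted logistic outcome regressions per arm: consistent if
#'     either the outcome model or the propensity model is correct.
#' }
#'
#' @param confounders Numeric matrix (trimmed sample).
#' @param exposure,outcome Binary vectors.
#' @param scores Propensity scores (trimmed sample).
#' @param seed Seed for the outcome-model cross-fitting folds.
#' @param n_folds Cross-fitting folds for the AIPW outcome models.
#' @return List of two [effect_estimate()]s (`ipw_means`, `aipw`), each with
#'   `extra` fields `rd` (risk difference), `var_rd`, and marginal risks.
#' @export
alt_estimators <- function(confounders, exposure, outcome, scores,
                           seed = 1L, n_folds = 2L) {
  confounders <- as.matrix(confounders)
  exposure <- as.integer(exposure)
  outcome <- as.integer(outcome)
  n <- length(outcome)
  if (inherits(scores, "propensity_result")) scores <- scores$scores
  stopifnot(nrow(confounders) == n, length(scores) == n)
  e <- pmin(pmax(scores, 1e-4), 1 - 1e-4)

  wrap <- function(method, mu1, mu0, if1, if0) {
    rd <- mu1 - mu0
    var_rd <- var(if1 - if0) / n
    ## delta method to the log-OR scale
    grad1 <- 1 / (mu1 * (1 - mu1))
    grad0 <- -1 / (mu0 * (1 - mu0))
    log_or <- qlogis(mu1) - qlogis(mu0)
    var_lor <- var(grad1 * if1 + grad0 * if0) / n
    ws <- wald_summary(log_or, var_lor)
    effect_estimate(method, log_or = log_or, var_log_or = var_lor,
                    ci95 = ws$ci95, p_one_sided = ws$p_one_sided,
                    rrr = 1 - mu1 / mu0,
                    n_exposed = sum(exposure == 1L),
                    n_unexposed = sum(exposure == 0L),
                    extra = list(rd = rd, var_rd = var_rd,
                                 se_rd = sqrt(var_rd), mu1 = mu1, mu0 = mu0))
  }

  ## Hajek IPW, ATT weights
  w0 <- e / (1 - e)
  mu1 <- mean(outcome[exposure == 1L])
  mu0 <- weighted.mean(outcome[exposure == 0L], w0[exposure == 0L])
  p1 <- mean(exposure == 1L)
  if1 <- exposure * (outcome - mu1) / p1
  if0 <- (1 - exposure) * w0 * (outcome - mu0) / mean((1 - exposure) * w0)
  ipw_est <- if (mu0 == 0 || mu0 == 1 || mu1 == 0 || mu1 == 1) {
    rd_only(mu1, mu0, if1, if0, n, exposure, "ipw_means")
  } else wrap("ipw_means", mu1, mu0, if1, if0)

  ## AIPW with cross-fitted outcome regressions
  folds <- with_seed(derive_seed(seed, "aipw-folds"),
                     sample(rep_len(seq_len(n_folds), n)))
  m1 <- m0 <- numeric(n)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    te <- folds == f
    fit_arm <- function(arm) {
      sel <- tr & exposure == arm
      df <- data.frame(.y = outcome[sel], confounders[sel, , drop = FALSE])
      fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
      predict(fit, newdata = data.frame(confounders[te, , drop = FALSE]),
              type = "response")
    }
    m1[te] <- fit_arm(1L)
    m0[te] <- fit_arm(0L)
  }
  psi1 <- m1 + exposure * (outcome - m1) / e
  psi0 <- m0 + (1 - exposure) * (outcome - m0) / (1 - e)
  a1 <- mean(psi1)
  a0 <- mean(psi0)
  aipw_est <- if (a0 <= 0 || a0 >= 1 || a1 <= 0 || a1 >= 1) {
    rd_only(a1, a0, psi1 - a1, psi0 - a0, n, exposure, "aipw")
  } else wrap("aipw", a1, a0, psi1 - a1, psi0 - a0)

  list(ipw_means = ipw_est, aipw = aipw_est)
}

# Degenerate marginal risks (0 or 1): report the risk difference only.
rd_only <- function(mu1, mu0, if1, if0, n, exposure, method) {
  rd <- mu1 - mu0
  var_rd <- var(if1 - if0) / n
  effect_estimate(method, log_or = NA_real_, var_log_or = NA_real_,
                  ci95 = c(NA_real_, NA_real_), p_one_sided = NA_real_,
                  rrr = if (mu0 > 0) 1 - mu1 / mu0 else NA_real_,
                  n_exposed = sum(exposure == 1L),
                  n_unexposed = sum(exposure == 0L),
                  extra = list(rd = rd, var_rd = var_rd, se_rd = sqrt(var_rd),
                               mu1 = mu1, mu0 = mu0))
}

#' Rerun a study under a shortened exposure window
#'
#' Redefines exposure by requiring regular use within the prior
#' `window_days` (90 by default, i.e. 3 months) instead of the prior year,
#' reruns cohort construction, estimation and federation, and reports the
#' two result sets side by side along with the per-source Jaccard overlap of
#' the exposed patient sets.
#'
#' @param config A [study_config()].
#' @param window_days Shortened MPR lookback (default 90).
#' @return List with `original` and `variant` study bundles and
#'   `exposed_jaccard`, the per-source Jaccard index of exposed ids.
#' @export
exposure_window_variant <- function(config, window_days = 90) {
  stopifnot(inherits(config, "study_config"))
  variant_cfg <- config
  variant_cfg$specs <- lapply(config$specs, function(sp) {
    sp$mpr_window_days <- as.integer(window_days)
    sp
  })
  variant_cfg$output_dir <- NULL
  base_cfg <- config
  base_cfg$output_dir <- NULL
  orig <- run_study(base_cfg)
  vari <- run_study(variant_cfg)
  jac <- mapply(function(co, cv) {
    a <- co$patient_id[co$exposure == 1L]
    b <- cv$patient_id[cv$exposure == 1L]
    if (length(union(a, b)) == 0) return(NA_real_)
    length(intersect(a, b)) / length(union(a, b))
  }, orig$cohorts[[1]], vari$cohorts[[1]])
  list(original = orig, variant = vari, exposed_jaccard = jac)
}
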