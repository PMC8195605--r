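#' Greedy 5:1 exact-age Mahalanobis matching
#'
#' For each exposed patient (processed in a seed-shuffled deterministic
#' order), selects up to `ratio` unexposed patients of identical integer age,
#' without replacement, ranked by Mahalanobis distance on the standardized
#' non-age confounders, subject to a caliper. The default caliper is 0.2
#' standard deviations of the logit propensity score (the conventional
#' reading); `caliper_metric = "mahalanobis"` instead applies the caliper
#' directly to the Mahalanobis distance. Exposed patients with no admissible
#' candidate are dropped and counted. Each stratum's 2x2 table tallies the
#' exposed patient's outcome against the matched group's.
#'
#' Matching is intended to run on the trimmed (common-support) sample; pass
#' the cohort rows selected by [trim_overlap()].
#'
#' @param cohort A `cohort` (already restricted to the trimmed sample).
#' @param scores Propensity scores aligned with `cohort` rows.
#' @param seed Integer seed for the processing order.
#' @param outcome Outcome column used for the stratum tables.
#' @param ratio Maximum matches per exposed patient (default 5).
#' @param caliper Caliper width (default 0.2).
#' @param caliper_metric `"logit_ps"` (default) or `"mahalanobis"`.
#' @return A `matched_strata` object: per-stratum ids and
#'   [contingency_table()]s, the stratum count `k`, and the number of
#'   unmatched exposed patients.
#' @export
match_5to1 <- function(cohort, scores, seed = 1L,
                       outcome = "outcome_vent_death", ratio = 5L,
                       caliper = 0.2,
                       caliper_metric = c("logit_ps", "mahalanobis")) {
  caliper_metric <- match.arg(caliper_metric)
  exposure <- cohort$exposure
  if (!any(exposure == 1L)) stop("no exposed patients to match")
  y <- cohort[[outcome]]
  stopifnot(length(scores) == nrow(cohort), !is.null(y))

  X <- confounder_matrix(cohort, drop = "conf_age")
  keep_cols <- apply(X, 2, function(v) sd(v) > 0)
  X <- X[, keep_cols, drop = FALSE]
  S <- cov(X) + diag(1e-8, ncol(X))
  Sinv <- solve(S)

  lps <- qlogis(pmin(pmax(scores, 1e-6), 1 - 1e-6))
  cal_lps <- caliper * sd(lps)

  exp_idx <- which(exposure == 1L)
  ord <- with_seed(derive_seed(seed, "match-order"), sample(length(exp_idx)))
  exp_idx <- exp_idx[ord]

  ## unexposed candidates bucketed by exact integer age
  unexp_idx <- which(exposure == 0L)
  by_age <- split(unexp_idx, cohort$age[unexp_idx])
  used <- logical(nrow(cohort))

  strata <- vector("list", length(exp_idx))
  n_unmatched <- 0L
  ki <- 0L
  for (i in exp_idx) {
    cand <- by_age[[as.character(cohort$age[i])]]
    cand <- cand[!used[cand]]
    if (length(cand)) {
      D <- X[cand, , drop = FALSE] -
        matrix(X[i, ], length(cand), ncol(X), byrow = TRUE)
      d2 <- rowSums((D %*% Sinv) * D)
      d <- sqrt(pmax(d2, 0))
      admissible <- if (caliper_metric == "logit_ps") {
        abs(lps[cand] - lps[i]) <= cal_lps
      } else {
        d <= caliper
      }
      cand <- cand[admissible]
      d <- d[admissible]
    }
    if (!length(cand)) {
      n_unmatched <- n_unmatched + 1L
      next
    }
    sel <- cand[order(d, cand)][seq_len(min(ratio, length(cand)))]
    used[sel] <- TRUE
    ki <- ki + 1L
    strata[[ki]] <- list(
      exposed_id = cohort$patient_id[i],
      matched_unexposed_ids = cohort$patient_id[sel],
      exposed_idx = i, matched_idx = sel,
      table = contingency_table(y[i], 1L - y[i], sum(y[sel]),
                                length(sel) - sum(y[sel]))
    )
  }
  strata <- strata[seq_len(ki)]
  structure(list(strata = strata, k = ki, n_unmatched = n_unmatched,
                 outcome = outcome),
            class = "matched_strata")
}

#' @export
print.matched_strata <- function(x, ...) {
  cat("<matched_strata> k =", x$k, "strata;", x$n_unmatched,
      "exposed patients unmatched\n")
  invisible(x)
}

#' Re-tabulate matched strata for a different outcome
#'
#' @param matched A `matched_strata` from [match_5to1()].
#' @param outcome_by_id Named 0/1 vector of outcomes keyed by patient id.
#' @return List of per-stratum [contingency_table()]s.
#' @export
strata_tables <- function(matched, outcome_by_id = NULL) {
  if (is.null(outcome_by_id)) return(lapply(matched$strata, `[[`, "table"))
  outcome_by_id <- unlist(outcome_by_id)
  lapply(matched$strata, function(s) {
    ye <- unname(outcome_by_id[s$exposed_id])
    ym <- unname(outcome_by_id[s$matched_unexposed_ids])
    contingency_table(ye, 1L - ye, sum(ym), length(ym) - sum(ym))
  })
}

# Mantel-Haenszel machinery on stratified 2x2 tables. Strata that carry no
# margin information (any zero row or column margin, or n < 2) contribute
# nothing and are dropped before the sums.
mh_components <- function(tables) {
  a <- vapply(tables, `[[`, numeric(1), "a")
  b <- vapply(tables, `[[`, numeric(1), "b")
  cc <- vapply(tables, `[[`, numeric(1), "c")
  d <- vapply(tables, `[[`, numeric(1), "d")
  n <- a + b + cc + d
  informative <- n >= 2 & (a + b) > 0 & (cc + d) > 0 & (a + cc) > 0 & (b + d) > 0
  list(a = a[informative], b = b[informative], c = cc[informative],
       d = d[informative], n = n[informative],
       n_dropped = sum(!informative))
}

#' Cochran-Mantel-Haenszel common odds ratio test
#'
#' Over a set of stratified 2x2 tables (matched sets, or one table per source
#' database in federated pooling), computes the Mantel-Haenszel common odds
#' ratio, a 95% CI from the Robins-Breslow-Greenland variance of its log, and
#' the CMH test statistic without continuity correction. The one-sided
#' p-value is the normal tail of the signed CMH statistic in the protective
#' direction (fewer exposed outcomes than expected under the null). An RRR is
#' also reported from the margin-summed table when defined.
#'
#' @param strata A `matched_strata`, a list of [contingency_table()]s, or a
#'   single `contingency_table`.
#' @param method Label for the resulting estimate (default `"matched"`;
#'   federated callers pass `"unadjusted"`).
#' @return An [effect_estimate()]. The stratum count used is recorded in
#'   `extra$k` along with the number of degenerate strata dropped.
#' @export
cmh_test <- function(strata, method = "matched") {
  tables <- if (inherits(strata, "matched_strata")) strata_tables(strata)
            else if (inherits(strata, "contingency_table")) list(strata)
            else strata
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "contingency_table")))
  mc <- mh_components(tables)
  if (length(mc$a) == 0) stop("all strata are degenerate: no margin information")

  R <- sum(mc$a * mc$d / mc$n)
  S <- sum(mc$b * mc$c / mc$n)
  if (R == 0 || S == 0) {
    stop("Mantel-Haenszel odds ratio degenerate (zero cross-product sum)")
  }
  or_mh <- R / S

  ## Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (mc$a + mc$d) / mc$n
  Q <- (mc$b + mc$c) / mc$n
  r <- mc$a * mc$d / mc$n
  s <- mc$b * mc$c / mc$n
  var_log <- sum(P * r) / (2 * R^2) + sum(P * s + Q * r) / (2 * R * S) +
    sum(Q * s) / (2 * S^2)

  ## CMH statistic, no continuity correction, signed for the one-sided test
  n1 <- mc$a + mc$b
  n0 <- mc$c + mc$d
  m1 <- mc$a + mc$c
  m0 <- mc$b + mc$d
  expect <- n1 * m1 / mc$n
  vr <- n1 * n0 * m1 * m0 / (mc$n^2 * (mc$n - 1))
  z <- (sum(mc$a) - sum(expect)) / sqrt(sum(vr))

  tot <- contingency_table(sum(mc$a), sum(mc$b), sum(mc$c), sum(mc$d))
  rr <- tryCatch(compute_rrr(tot),
                 error = function(e) list(rrr = NA_real_, var_rrr = NA_real_))

  effect_estimate(method, log_or = log(or_mh), var_log_or = var_log,
                  ci95 = exp(log(or_mh) + c(-1, 1) * 1.96 * sqrt(var_log)),
                  p_one_sided = pnorm(z),
                  rrr = rr$rrr, var_rrr = rr$var_rrr,
                  n_exposed = sum(mc$a + mc$b), n_unexposed = sum(mc$c + mc$d),
                  extra = list(k = length(mc$a), n_dropped = mc$n_dropped,
                               cmh_z = z, cmh_chisq = z^2))
}
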