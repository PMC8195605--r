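#' Exposure-by-outcome 2x2 contingency table
#'
#' Cell convention: `a` exposed with outcome, `b` exposed without, `c`
#' unexposed with outcome, `d` unexposed without.
#'
#' @param a,b,c,d Nonnegative counts.
#' @return A `contingency_table` object.
#' @export
#' @examples
#' contingency_table(4, 1, 2, 3)
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "contingency_table")
}

#' @rdname contingency_table
#' @param cohort A `cohort` from [build_cohort()].
#' @param outcome Outcome column name (e.g. `"outcome_vent_death"`).
#' @export
cohort_table <- function(cohort, outcome = "outcome_vent_death") {
  y <- cohort[[outcome]]
  e <- cohort$exposure
  contingency_table(sum(y == 1 & e == 1), sum(y == 0 & e == 1),
                    sum(y == 1 & e == 0), sum(y == 0 & e == 0))
}

as_matrix_ct <- function(tab) {
  matrix(c(tab$a, tab$b, tab$c, tab$d), nrow = 2, byrow = TRUE,
         dimnames = list(exposure = c("exposed", "unexposed"),
                         outcome = c("yes", "no")))
}

#' @export
print.contingency_table <- function(x, ...) {
  print(as_matrix_ct(x))
  invisible(x)
}

#' Construct an effect estimate record
#'
#' Common container for the unadjusted, adjusted and matched estimators and
#' for federated pooling: odds ratio and its log, the log-OR variance (the
#' adjusted model's coefficient variance when produced by [ipw_logistic()]),
#' a 95% CI, a one-sided p in the protective direction (OR < 1), the relative
#' risk reduction RRR = 1 - p_x/p_y with its delta-method variance, and arm
#' sizes.
#'
#' @param method One of `"unadjusted"`, `"adjusted"`, `"matched"`,
#'   `"ipw_means"`, `"aipw"`.
#' @param log_or Log odds ratio point estimate.
#' @param var_log_or Variance of the log OR (`NA` when not defined, e.g. the
#'   exact conditional estimator).
#' @param ci95 Length-2 CI for the OR.
#' @param p_one_sided One-sided p-value, protective direction.
#' @param rrr,var_rrr Relative risk reduction and its variance.
#' @param n_exposed,n_unexposed Arm sizes.
#' @param extra Optional list of method-specific fields.
#' @return An `effect_estimate` object.
#' @export
effect_estimate <- function(method, log_or, var_log_or, ci95, p_one_sided,
                            rrr = NA_real_, var_rrr = NA_real_,
                            n_exposed = NA_integer_, n_unexposed = NA_integer_,
                            extra = list()) {
  if (is.finite(var_log_or) && var_log_or < 0) stop("negative variance")
  stopifnot(length(ci95) == 2L)
  structure(list(method = method, or_point = exp(log_or), log_or = log_or,
                 var_log_or = var_log_or, ci95 = ci95,
                 p_one_sided = p_one_sided, rrr = rrr, var_rrr = var_rrr,
                 n_exposed = n_exposed, n_unexposed = n_unexposed,
                 extra = extra),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate: %s>\n", x$method))
  cat(sprintf("  OR %.3f  95%% CI (%.3f-%.3f)  one-sided p %.4g\n",
              x$or_point, x$ci95[1], x$ci95[2], x$p_one_sided))
  if (is.finite(x$rrr)) {
    cat(sprintf("  RRR %.1f%%  Var(RRR) %.4g\n", 100 * x$rrr, x$var_rrr))
  }
  cat(sprintf("  n exposed %s / unexposed %s\n", x$n_exposed, x$n_unexposed))
  invisible(x)
}

#' One-sided Fisher probability in the protective direction
#'
#' Tail probability, under the central hypergeometric null with all margins
#' fixed, of a table with at most `a` exposed outcomes -- i.e. at least as
#' extreme in the protective (OR < 1) direction.
#'
#' @param tab A [contingency_table()].
#' @return The one-sided p-value.
#' @export
fisher_one_sided_p <- function(tab) {
  m <- tab$a + tab$b   # exposed margin
  n <- tab$c + tab$d   # unexposed margin
  k <- tab$a + tab$c   # outcome margin
  sum(dhyper(0:tab$a, m, n, k))
}

#' Unadjusted exact analysis of a 2x2 table
#'
#' Odds ratio (conditional maximum likelihood under the noncentral
#' hypergeometric model) and exact conditional 95% CI via [fisher.test()];
#' the one-sided p-value is the hypergeometric tail in the protective
#' direction ([fisher_one_sided_p()]); RRR and its variance via
#' [compute_rrr()].
#'
#' @param tab A [contingency_table()]; both exposure margins must be positive
#'   and both outcome margins must be positive.
#' @return An [effect_estimate()] with `method = "unadjusted"`.
#' @export
fisher_unadjusted <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  if (tab$a + tab$b == 0 || tab$c + tab$d == 0 ||
      tab$a + tab$c == 0 || tab$b + tab$d == 0) {
    stop("degenerate table: a zero margin leaves the odds ratio unidentified")
  }
  ft <- fisher.test(as_matrix_ct(tab), conf.level = 0.95)
  rr <- compute_rrr(tab)
  effect_estimate("unadjusted",
                  log_or = log(unname(ft$estimate)),
                  var_log_or = NA_real_,
                  ci95 = as.numeric(ft$conf.int),
                  p_one_sided = fisher_one_sided_p(tab),
                  rrr = rr$rrr, var_rrr = rr$var_rrr,
                  n_exposed = tab$a + tab$b, n_unexposed = tab$c + tab$d)
}

#' Relative risk reduction and its delta-method variance
#'
#' RRR = 1 - p_x/p_y with p_x = a/(a+b) (exposed) and p_y = c/(c+d)
#' (unexposed). The variance is the first-order expansion of the ratio of two
#' independent binomial proportions:
#' \deqn{Var(RRR) = \frac{1}{n_x}\frac{p_x(1-p_x)}{p_y^2} +
#'       \frac{1}{n_y}\frac{p_x^2\, p_y(1-p_y)}{p_y^4}.}
#' It is a first-order approximation: accurate when the coefficient of
#' variation of p_y is small, and an underestimate for small unexposed arms.
#'
#' @param tab A [contingency_table()] with `c + d > 0` and `c > 0`.
#' @return List with `rrr` and `var_rrr`.
#' @export
#' @examples
#' compute_rrr(contingency_table(10, 90, 20, 80)) # rrr 0.5, var 0.0325
compute_rrr <- function(tab) {
  nx <- tab$a + tab$b
  ny <- tab$c + tab$d
  if (ny == 0 || tab$c == 0) stop("undefined RRR: unexposed outcome probability is zero")
  if (nx == 0) stop("undefined RRR: empty exposed arm")
  px <- tab$a / nx
  py <- tab$c / ny
  list(rrr = 1 - px / py,
       var_rrr = (1 / nx) * px * (1 - px) / py^2 +
                 (1 / ny) * px^2 * py * (1 - py) / py^4)
}
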