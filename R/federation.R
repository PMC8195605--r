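#' Federated pooling of per-source results
#'
#' These operations consume only aggregate objects -- per-source
#' [effect_estimate()]s, [contingency_table()]s, or matched stratum tables --
#' never patient-level data, mirroring a setting where data use agreements
#' prohibit combining raw records across sources.
#'
#' `pool_coefficients()` combines adjusted-model exposure coefficients by
#' inverse-variance weighting:
#' \deqn{\beta_{pooled} = \frac{\sum_i \beta_i / Var(\beta_i)}
#'   {\sum_i 1 / Var(\beta_i)}, \qquad
#'   Var(\beta_{pooled}) = \frac{1}{\sum_i 1 / Var(\beta_i)}.}
#'
#' @param estimates List of [effect_estimate()]s, each with finite positive
#'   `var_log_or`.
#' @param sources Optional character labels.
#' @return A `pooled_result`: `beta_pooled`, `var_pooled`, `or_pooled`, a
#'   Wald 95% CI, the one-sided protective p recomputed from the pooled
#'   statistic (never combined from per-source p-values), pooled RRR when all
#'   inputs carry one, total n, sources and method.
#' @export
pool_coefficients <- function(estimates, sources = NULL) {
  stopifnot(length(estimates) >= 1)
  v <- vapply(estimates, `[[`, numeric(1), "var_log_or")
  b <- vapply(estimates, `[[`, numeric(1), "log_or")
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all estimates must carry a finite positive var_log_or ",
         "(a zero variance would take infinite weight)")
  }
  wsum <- sum(1 / v)
  beta <- sum(b / v) / wsum
  var_b <- 1 / wsum
  ws <- wald_summary(beta, var_b)
  rrr <- vapply(estimates, `[[`, numeric(1), "rrr")
  vr <- vapply(estimates, `[[`, numeric(1), "var_rrr")
  pr <- if (all(is.finite(rrr)) && all(is.finite(vr)) && all(vr > 0)) {
    pool_rrr(rrr = rrr, var_rrr = vr)
  } else list(rrr_pooled = NA_real_, var_rrr_pooled = NA_real_)
  pooled_result(
    beta_pooled = beta, var_pooled = var_b, ci95 = ws$ci95,
    p_one_sided = ws$p_one_sided,
    rrr_pooled = pr$rrr_pooled, var_rrr_pooled = pr$var_rrr_pooled,
    n_total = sum(vapply(estimates, function(e) {
      sum(c(e$n_exposed, e$n_unexposed), na.rm = TRUE)
    }, numeric(1))),
    sources = sources %||% paste0("source", seq_along(estimates)),
    method = estimates[[1]]$method
  )
}

#' @rdname pool_coefficients
#' @param tables One [contingency_table()] per source (at least 2). Each
#'   source contributes its table as one stratum of a CMH test; a source with
#'   an empty margin contributes nothing (the result then equals the other
#'   sources alone).
#' @export
pool_unadjusted <- function(tables, sources = NULL) {
  stopifnot(length(tables) >= 2)
  est <- cmh_test(tables, method = "unadjusted")
  rrrs <- lapply(tables, function(t) {
    tryCatch(compute_rrr(t), error = function(e) NULL)
  })
  ok <- !vapply(rrrs, is.null, logical(1))
  pr <- if (sum(ok) >= 1 && all(vapply(rrrs[ok], `[[`, numeric(1), "var_rrr") > 0)) {
    pool_rrr(rrr = vapply(rrrs[ok], `[[`, numeric(1), "rrr"),
             var_rrr = vapply(rrrs[ok], `[[`, numeric(1), "var_rrr"))
  } else list(rrr_pooled = NA_real_, var_rrr_pooled = NA_real_)
  pooled_result(
    beta_pooled = est$log_or, var_pooled = est$var_log_or, ci95 = est$ci95,
    p_one_sided = est$p_one_sided,
    rrr_pooled = pr$rrr_pooled, var_rrr_pooled = pr$var_rrr_pooled,
    n_total = est$n_exposed + est$n_unexposed,
    sources = sources %||% paste0("source", seq_along(tables)),
    method = "unadjusted", k = est$extra$k
  )
}

#' @rdname pool_coefficients
#' @param strata_by_source List of `matched_strata` (one per source). Their
#'   stratum tables are concatenated -- the exposed populations and their
#'   matched sets are pooled without ever combining raw data -- and evaluated
#'   by one CMH test over the 2 x 2 x (k_1 + ... + k_m) array.
#' @export
pool_matched <- function(strata_by_source, sources = NULL) {
  stopifnot(length(strata_by_source) >= 1,
            all(vapply(strata_by_source, inherits, logical(1), "matched_strata")))
  tables <- do.call(c, lapply(strata_by_source, strata_tables))
  est <- cmh_test(tables, method = "matched")
  pooled_result(
    beta_pooled = est$log_or, var_pooled = est$var_log_or, ci95 = est$ci95,
    p_one_sided = est$p_one_sided,
    rrr_pooled = est$rrr, var_rrr_pooled = est$var_rrr,
    n_total = est$n_exposed + est$n_unexposed,
    sources = sources %||% paste0("source", seq_along(strata_by_source)),
    method = "matched",
    k = as.integer(sum(vapply(strata_by_source, function(m) as.numeric(m$k),
                              numeric(1))))
  )
}

#' @rdname pool_coefficients
#' @param rrr,var_rrr Numeric vectors of per-source RRR estimates and their
#'   variances (used when calling `pool_rrr()` directly; otherwise extracted
#'   from `estimates`).
#' @export
pool_rrr <- function(estimates = NULL, rrr = NULL, var_rrr = NULL) {
  if (!is.null(estimates)) {
    rrr <- vapply(estimates, `[[`, numeric(1), "rrr")
    var_rrr <- vapply(estimates, `[[`, numeric(1), "var_rrr")
  }
  stopifnot(length(rrr) >= 1, length(rrr) == length(var_rrr))
  if (any(!is.finite(var_rrr)) || any(var_rrr <= 0)) {
    stop("all RRR variances must be finite and positive")
  }
  wsum <- sum(1 / var_rrr)
  list(rrr_pooled = sum(rrr / var_rrr) / wsum, var_rrr_pooled = 1 / wsum)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pooled_result <- function(beta_pooled, var_pooled, ci95, p_one_sided,
                          rrr_pooled, var_rrr_pooled, n_total, sources,
                          method, k = NA_integer_) {
  structure(list(beta_pooled = beta_pooled, var_pooled = var_pooled,
                 or_pooled = exp(beta_pooled), ci95 = ci95,
                 p_one_sided = p_one_sided, rrr_pooled = rrr_pooled,
                 var_rrr_pooled = var_rrr_pooled, n_total = n_total,
                 sources = sources, method = method, k = k),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("<pooled_result: %s over %s>\n", x$method,
              paste(x$sources, collapse = " + ")))
  cat(sprintf("  OR %.3f  95%% CI (%.3f-%.3f)  one-sided p %.4g  n %d\n",
              x$or_pooled, x$ci95[1], x$ci95[2], x$p_one_sided, x$n_total))
  if (is.finite(x$rrr_pooled)) cat(sprintf("  pooled RRR %.1f%%\n", 100 * x$rrr_pooled))
  invisible(x)
}
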