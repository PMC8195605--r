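#' Cross-fitted nonparametric propensity scores
#'
#' Estimates e(x) = P(exposure = 1 | confounders) with a cross-fitted
#' ensemble: each patient's score is predicted by a model trained on the
#' other folds, so scores are out-of-sample ("honest") for every patient.
#' The default learner is gradient-boosted trees (exact greedy splits, no row
#' subsampling); `method = "ranger"` uses a probability forest instead.
#'
#' Fold membership is a deterministic hash of the covariate row (not the row
#' index), and training rows are fed to the learner in hash order. Two
#' consequences: identical `(confounders, exposure, seed)` give identical
#' scores, and permuting the patients permutes the scores identically.
#'
#' @param confounders Numeric matrix, one row per patient, no missing values.
#' @param exposure Binary vector (0/1), at least 2 patients per arm.
#' @param seed Integer seed.
#' @param method `"xgboost"` (default) or `"ranger"`.
#' @param n_folds Cross-fitting folds (default 2).
#' @param nrounds,max_depth,eta Boosting hyperparameters (xgboost only).
#' @param num_trees Forest size (ranger only).
#' @return A `propensity_result`: `scores` strictly inside (0, 1), plus
#'   `method` and `folds`. Pass to [trim_overlap()] to obtain bounds and the
#'   retained set.
#' @export
fit_propensity <- function(confounders, exposure, seed = 1L,
                           method = c("xgboost", "ranger"), n_folds = 2L,
                           nrounds = 100L, max_depth = 3L, eta = 0.1,
                           num_trees = 200L) {
  method <- match.arg(method)
  confounders <- as.matrix(confounders)
  exposure <- as.integer(exposure)
  n <- nrow(confounders)
  stopifnot(length(exposure) == n, all(exposure %in% c(0L, 1L)))
  if (anyNA(confounders)) stop("missing confounder values")
  if (sum(exposure == 1L) < 2L || sum(exposure == 0L) < 2L) {
    stop("need at least 2 patients per arm to estimate propensity scores")
  }

  ## deterministic, permutation-equivariant fold hash of the covariate row
  w <- sqrt(c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47,
              53, 59, 61, 67, 71))[seq_len(min(ncol(confounders), 20))]
  h <- as.numeric(confounders[, seq_along(w), drop = FALSE] %*% w) +
    seed * 0.6180339887498949
  u <- abs(sin(h * 12.9898 + 78.233) * 43758.5453)
  u <- u - floor(u)
  folds <- 1L + pmin(floor(u * n_folds), n_folds - 1)

  ## degenerate hash split (e.g. constant covariates): fall back to a seeded
  ## stratified split; equivariance is vacuous there
  bad <- any(vapply(seq_len(n_folds), function(f) {
    sum(exposure[folds == f] == 1L) < 1L || sum(folds != f) < 4L ||
      length(unique(exposure[folds != f])) < 2L
  }, logical(1)))
  if (bad) {
    folds <- with_seed(derive_seed(seed, "fallback-folds"),
                       sample(rep_len(seq_len(n_folds), n)))
  }

  scores <- numeric(n)
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    tr <- tr[order(u[tr], tr)] # canonical training order
    if (method == "xgboost") {
      with_seed(derive_seed(seed, "fold", f), {
        bst <- xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = eta,
                        max_depth = max_depth, min_child_weight = 10,
                        subsample = 1, colsample_bytree = 1,
                        tree_method = "exact", nthread = 1),
          data = xgboost::xgb.DMatrix(confounders[tr, , drop = FALSE],
                                      label = exposure[tr]),
          nrounds = nrounds, verbose = 0)
        scores[te] <- predict(bst, xgboost::xgb.DMatrix(
          confounders[te, , drop = FALSE]))
      })
    } else {
      if (!requireNamespace("ranger", quietly = TRUE)) {
        stop("method = 'ranger' requires the ranger package")
      }
      df <- data.frame(.y = factor(exposure[tr], levels = c(0, 1)),
                       confounders[tr, , drop = FALSE])
      fit <- ranger::ranger(.y ~ ., data = df, probability = TRUE,
                            num.trees = num_trees, num.threads = 1,
                            seed = derive_seed(seed, "fold", f))
      pr <- predict(fit, data.frame(confounders[te, , drop = FALSE]),
                    num.threads = 1)$predictions
      scores[te] <- pr[, "1"]
    }
  }
  scores <- pmin(pmax(scores, 1e-4), 1 - 1e-4)
  structure(list(scores = scores, method = method, folds = folds,
                 lower_bound = NA_real_, upper_bound = NA_real_,
                 kept_ids = NULL),
            class = "propensity_result")
}

#' Overlap trimming by cross-arm percentile bounds
#'
#' Restricts the analysis to patients whose propensity score lies in the
#' common-support band: the lower bound is the larger of the two arms' 1st
#' percentiles, the upper bound the smaller of the two arms' 99th percentiles
#' (closed interval; quantiles by linear interpolation).
#'
#' @param result A `propensity_result` from [fit_propensity()], or a bare
#'   numeric score vector.
#' @param exposure Binary vector aligned with the scores.
#' @param probs Percentile pair, default `c(0.01, 0.99)`.
#' @return The `propensity_result` with `lower_bound`, `upper_bound`, a
#'   logical `keep` vector and `kept_ids` (indices) filled in.
#' @export
trim_overlap <- function(result, exposure, probs = c(0.01, 0.99)) {
  scores <- if (inherits(result, "propensity_result")) result$scores else result
  exposure <- as.integer(exposure)
  stopifnot(length(exposure) == length(scores))
  if (!any(exposure == 1L) || !any(exposure == 0L)) stop("both arms must be nonempty")
  lb <- max(quantile(scores[exposure == 1L], probs[1], type = 7),
            quantile(scores[exposure == 0L], probs[1], type = 7))
  ub <- min(quantile(scores[exposure == 1L], probs[2], type = 7),
            quantile(scores[exposure == 0L], probs[2], type = 7))
  if (lb > ub) {
    stop("empty overlap region: propensity supports of the two arms are disjoint")
  }
  keep <- scores >= lb & scores <= ub
  out <- if (inherits(result, "propensity_result")) result else {
    structure(list(scores = scores, method = "external", folds = NULL),
              class = "propensity_result")
  }
  out$lower_bound <- unname(lb)
  out$upper_bound <- unname(ub)
  out$keep <- keep
  out$kept_ids <- which(keep)
  out
}

#' Inverse-propensity-weighted logistic outcome model
#'
#' Fits outcome ~ exposure + confounders by weighted logistic regression on
#' the trimmed sample. Default weights target the treated population (ATT):
#' exposed patients get weight 1 and unexposed patients e(x)/(1 - e(x)), so
#' the reweighted unexposed arm resembles the exposed arm. `estimand = "ate"`
#' uses 1/e and 1/(1 - e) instead. The exposure coefficient is the log OR;
#' its variance comes from the heteroskedasticity-robust sandwich estimator,
#' giving a Wald CI and a one-sided p in the protective direction. The
#' reported RRR uses Hajek-weighted outcome probabilities with effective
#' (Kish) arm sizes in the delta-method variance.
#'
#' @param confounders Numeric matrix (trimmed sample).
#' @param exposure,outcome Binary vectors (trimmed sample); the outcome must
#'   have both classes.
#' @param scores Propensity scores (trimmed sample), or a
#'   `propensity_result` whose `keep` selection has already been applied.
#' @param estimand `"att"` (default) or `"ate"`.
#' @return An [effect_estimate()] with `method = "adjusted"`.
#' @export
ipw_logistic <- function(confounders, exposure, outcome, scores,
                         estimand = c("att", "ate")) {
  estimand <- match.arg(estimand)
  if (inherits(scores, "propensity_result")) scores <- scores$scores
  confounders <- as.matrix(confounders)
  exposure <- as.integer(exposure)
  outcome <- as.integer(outcome)
  n <- length(outcome)
  stopifnot(nrow(confounders) == n, length(exposure) == n, length(scores) == n)
  if (length(unique(outcome)) < 2L) stop("outcome must have both classes")

  w <- if (estimand == "att") ifelse(exposure == 1L, 1, scores / (1 - scores))
       else ifelse(exposure == 1L, 1 / scores, 1 / (1 - scores))
  df <- data.frame(.y = outcome, .expo = exposure, confounders)
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = quasibinomial(),
                              weights = w))
  beta <- coef(fit)[".expo"]
  if (!fit$converged || !is.finite(beta) || abs(beta) > 15) {
    stop("ipw_logistic did not converge (possible separation); ",
         "exposure coefficient = ", format(beta),
         ", events = ", sum(outcome), "/", n)
  }
  vc <- sandwich::vcovHC(fit, type = "HC0")
  var_beta <- vc[".expo", ".expo"]
  ws <- wald_summary(unname(beta), var_beta)

  px <- weighted.mean(outcome[exposure == 1L], w[exposure == 1L])
  py <- weighted.mean(outcome[exposure == 0L], w[exposure == 0L])
  kish <- function(wi) sum(wi)^2 / sum(wi^2)
  rr <- if (py > 0) {
    nxe <- kish(w[exposure == 1L]); nye <- kish(w[exposure == 0L])
    list(rrr = 1 - px / py,
         var_rrr = (1 / nxe) * px * (1 - px) / py^2 +
                   (1 / nye) * px^2 * py * (1 - py) / py^4)
  } else list(rrr = NA_real_, var_rrr = NA_real_)

  effect_estimate("adjusted", log_or = unname(beta), var_log_or = var_beta,
                  ci95 = ws$ci95, p_one_sided = ws$p_one_sided,
                  rrr = rr$rrr, var_rrr = rr$var_rrr,
                  n_exposed = sum(exposure == 1L),
                  n_unexposed = sum(exposure == 0L),
                  extra = list(estimand = estimand))
}

#' Standardized mean differences before and after weighting
#'
#' SMD = (weighted mean exposed - weighted mean unexposed) / pooled SD per
#' covariate, where the pooled SD is the unweighted
#' sqrt((s1^2 + s0^2)/2). Zero pooled SD yields SMD 0 with a warning.
#'
#' @param confounders Numeric matrix.
#' @param exposure Binary vector.
#' @param weights Optional weights (e.g. ATT weights); `NULL` for unweighted.
#' @return Data frame with `covariate`, `smd_unweighted`, `smd_weighted`
#'   (equal to the unweighted column when `weights` is `NULL`).
#' @export
covariate_balance <- function(confounders, exposure, weights = NULL) {
  confounders <- as.matrix(confounders)
  exposure <- as.integer(exposure)
  if (is.null(weights)) weights <- rep(1, length(exposure))
  smd_one <- function(x, w) {
    s1 <- sd(x[exposure == 1L]); s0 <- sd(x[exposure == 0L])
    pooled <- sqrt((s1^2 + s0^2) / 2)
    if (!is.finite(pooled) || pooled == 0) {
      warning("zero pooled SD; SMD reported as 0")
      return(0)
    }
    (weighted.mean(x[exposure == 1L], w[exposure == 1L]) -
       weighted.mean(x[exposure == 0L], w[exposure == 0L])) / pooled
  }
  data.frame(
    covariate = colnames(confounders),
    smd_unweighted = apply(confounders, 2, smd_one, w = rep(1, length(exposure))),
    smd_weighted = apply(confounders, 2, smd_one, w = weights),
    row.names = NULL
  )
}
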