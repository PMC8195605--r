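test_that("fisher_unadjusted matches exact conditional inference", {
  sym <- fisher_unadjusted(contingency_table(10, 10, 10, 10))
  expect_equal(sym$or_point, 1, tolerance = 1e-6)
  expect_gt(sym$p_one_sided, 0.5)

  # enumeration oracle for (1,9,5,5): all tables with the observed margins,
  # central hypergeometric probabilities from binomial coefficients
  tab <- contingency_table(1, 9, 5, 5)
  m <- 10; n <- 10; k <- 6
  probs <- choose(m, 0:6) * choose(n, k - (0:6)) / choose(m + n, k)
  expect_equal(fisher_one_sided_p(tab), sum(probs[1:2]), tolerance = 1e-12)
  expect_equal(fisher_unadjusted(tab)$p_one_sided, sum(probs[1:2]), tolerance = 1e-12)

  # cross-check against stats::fisher.test on random tables
  set.seed(4)
  for (i in 1:20) {
    tb <- rand_table()
    ft <- fisher.test(matrix(c(tb$a, tb$b, tb$c, tb$d), 2, byrow = TRUE),
                      alternative = "less")
    expect_equal(fisher_one_sided_p(tb), ft$p.value, tolerance = 1e-10)
    est <- fisher_unadjusted(tb)
    ft2 <- fisher.test(matrix(c(tb$a, tb$b, tb$c, tb$d), 2, byrow = TRUE))
    expect_equal(est$or_point, unname(ft2$estimate), tolerance = 1e-8)
    expect_equal(est$ci95, as.numeric(ft2$conf.int), tolerance = 1e-8)
  }

  expect_error(fisher_unadjusted(contingency_table(0, 0, 5, 5)), "degenerate")
  expect_error(fisher_unadjusted(contingency_table(0, 5, 0, 5)), "degenerate")
})

test_that("compute_rrr evaluates the ratio-of-proportions formula exactly", {
  # p_x = p_y gives RRR 0
  expect_equal(compute_rrr(contingency_table(10, 40, 10, 40))$rrr, 0)
  # worked case: p_x = 0.1 (n 100), p_y = 0.2 (n 100)
  rr <- compute_rrr(contingency_table(10, 90, 20, 80))
  expect_equal(rr$rrr, 0.5)
  expect_equal(rr$var_rrr, 0.0225 + 0.01, tolerance = 1e-12)
  # boundary p_x = 0: RRR 1 with zero variance by the formula
  rr0 <- compute_rrr(contingency_table(0, 100, 20, 80))
  expect_equal(rr0$rrr, 1)
  expect_equal(rr0$var_rrr, 0)
  expect_error(compute_rrr(contingency_table(5, 5, 0, 10)), "undefined RRR")
})

test_that("RRR variance is a valid first-order approximation at moderate n", {
  # parametric bootstrap at n = 1000/arm, where the delta expansion holds
  vform <- compute_rrr(contingency_table(100, 900, 200, 800))$var_rrr
  set.seed(12)
  px <- rbinom(1e5, 1000, 0.1) / 1000
  py <- rbinom(1e5, 1000, 0.2) / 1000
  vboot <- var(1 - px / py)
  expect_lt(abs(vboot - vform) / vform, 0.05)
})

test_that("propensity scores are calibrated, discriminative and permutation-equivariant", {
  set.seed(21)
  # no-signal case: scores concentrate near the prevalence
  n <- 10000
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("x", 1:5)))
  e <- rbinom(n, 1, 0.3)
  ps <- fit_propensity(X, e, seed = 1)
  expect_lt(abs(mean(ps$scores) - 0.3), 0.02)
  expect_true(all(ps$scores > 0 & ps$scores < 1))

  # separable DGP: AUROC > 0.95
  n2 <- 5000
  X2 <- matrix(rnorm(n2 * 4), n2, dimnames = list(NULL, paste0("x", 1:4)))
  e2 <- as.integer(X2[, 1] > 0)
  ps2 <- fit_propensity(X2, e2, seed = 2)
  expect_gt(auroc(ps2$scores, e2), 0.95)

  # permuting patients permutes scores identically
  n3 <- 600
  X3 <- matrix(rnorm(n3 * 3), n3, dimnames = list(NULL, paste0("x", 1:3)))
  e3 <- rbinom(n3, 1, plogis(X3[, 1]))
  ps3 <- fit_propensity(X3, e3, seed = 3)
  perm <- sample(n3)
  ps3p <- fit_propensity(X3[perm, ], e3[perm], seed = 3)
  expect_equal(ps3p$scores, ps3$scores[perm], tolerance = 1e-12)

  expect_error(fit_propensity(X3, rep(1L, n3), seed = 1), "per arm")
})

test_that("trim_overlap implements the max-of-1st / min-of-99th percentile rule", {
  # planted grids with hand-computable type-7 quantiles
  exposed_scores <- seq(0, 1, by = 0.01)           # q01 = 0.01, q99 = 0.99
  unexposed_scores <- seq(0.2, 1, length.out = 101) # q01 = 0.208, q99 = 0.992
  scores <- c(exposed_scores, unexposed_scores)
  expo <- rep(c(1L, 0L), each = 101)
  tr <- trim_overlap(scores, expo)
  expect_equal(tr$lower_bound, 0.208, tolerance = 1e-12)
  expect_equal(tr$upper_bound, 0.99, tolerance = 1e-12)
  expect_identical(tr$kept_ids, which(scores >= 0.208 & scores <= 0.99))

  # identical distributions: about 2% trimmed by construction
  s2 <- rep(seq(0.001, 0.999, length.out = 500), 2)
  e2 <- rep(c(1L, 0L), each = 500)
  tr2 <- trim_overlap(s2, e2)
  expect_lt(mean(!tr2$keep), 0.03)
  expect_gt(mean(!tr2$keep), 0.01)

  # disjoint supports: empty overlap error
  set.seed(9)
  s3 <- c(runif(300, 0.6, 1), runif(300, 0, 0.4))
  e3 <- rep(c(1L, 0L), each = 300)
  expect_error(trim_overlap(s3, e3), "empty overlap")

  # degenerate: all scores equal keeps everyone
  tr4 <- trim_overlap(rep(0.4, 50), rep(c(1L, 0L), 25))
  expect_true(all(tr4$keep))
})

test_that("ipw_logistic recovers the null and reduces to plain logistic under unit weights", {
  set.seed(31)
  n <- 4000
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("x", 1:3)))
  e <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-2 + 0.5 * X[, 1]))
  est <- ipw_logistic(X, e, y, rep(0.5, n))
  expect_lt(abs(est$log_or), 2 * sqrt(est$var_log_or))

  # constant scores at prevalence 0.5 make all ATT weights 1: the point
  # estimate equals the ordinary logistic fit
  plain <- glm(y ~ e + X, family = binomial())
  expect_equal(est$log_or, unname(coef(plain)["e"]), tolerance = 1e-8)

  expect_error(ipw_logistic(X, e, rep(0L, n), rep(0.5, n)), "both classes")
})

test_that("ipw_logistic reports separation instead of a silent garbage fit", {
  set.seed(32)
  n <- 200
  X <- matrix(rnorm(n), n, dimnames = list(NULL, "x1"))
  e <- as.integer(X[, 1] > 0)
  y <- e # outcome perfectly determined by exposure
  expect_error(ipw_logistic(X, e, y, rep(0.5, n)), "converge|separation")
})

test_that("matching honors exact age, distances, calipers and no-replacement", {
  # an exact confounder duplicate is the first match (distance 0)
  conf <- cbind(conf_x1 = c(0, 0, 1.2, -0.8, 2.5, 0.4),
                conf_x2 = c(1, 1, -0.5, 0.3, 1.8, -1.2))
  co <- toy_cohort(exposure = c(1, 0, 0, 0, 0, 0), conf = conf)
  m <- match_5to1(co, scores = rep(0.3, 6), seed = 1,
                  caliper_metric = "mahalanobis", caliper = 100)
  expect_identical(m$strata[[1]]$matched_unexposed_ids[1], co$patient_id[2])

  # two exposed, one shared candidate at the same age: without replacement
  # leaves one unmatched
  conf2 <- cbind(conf_x1 = c(0, 0.1, 0.05, 5, -5),
                 conf_x2 = c(0, -0.1, 0.02, 5, -5))
  co2 <- toy_cohort(exposure = c(1, 1, 0, 0, 0),
                    age = c(60, 60, 60, 70, 70), conf = conf2)
  m2 <- match_5to1(co2, scores = rep(0.3, 5), seed = 2,
                   caliper_metric = "mahalanobis", caliper = 100)
  expect_identical(m2$k, 1L)
  expect_identical(m2$n_unmatched, 1L)

  # never matches across ages; never reuses an unexposed patient
  set.seed(40)
  n <- 400
  conf3 <- cbind(conf_x1 = rnorm(n), conf_x2 = rnorm(n), conf_x3 = rnorm(n))
  co3 <- toy_cohort(exposure = rbinom(n, 1, 0.25),
                    age = sample(58:62, n, TRUE), conf = conf3,
                    outcome = rbinom(n, 1, 0.2))
  sc <- plogis(rnorm(n, -1))
  m3 <- match_5to1(co3, sc, seed = 3)
  all_matched <- unlist(lapply(m3$strata, `[[`, "matched_unexposed_ids"))
  expect_identical(anyDuplicated(all_matched), 0L)
  age_of <- setNames(co3$age, co3$patient_id)
  for (s in m3$strata) {
    expect_true(all(age_of[s$matched_unexposed_ids] == age_of[s$exposed_id]))
  }
  expect_error(match_5to1(co3[co3$exposure == 0, ], sc[co3$exposure == 0]),
               "no exposed")
})

test_that("greedy selections equal a brute-force nearest-neighbor oracle on a planted cohort", {
  # 4 exposed patients, each planted with 5 uncontested near neighbors
  set.seed(41)
  centers <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6), 4, 2, byrow = TRUE)
  exp_conf <- centers
  near <- do.call(rbind, lapply(1:4, function(i) {
    sweep(matrix(rnorm(10, 0, 0.1), 5, 2), 2, centers[i, ], `+`)
  }))
  far <- matrix(rnorm(40, 0, 0.1), 20, 2) + 30
  conf <- rbind(exp_conf, near, far)
  colnames(conf) <- c("conf_x1", "conf_x2")
  co <- toy_cohort(exposure = c(rep(1, 4), rep(0, 40)), conf = conf)
  m <- match_5to1(co, scores = rep(0.3, 44), seed = 7,
                  caliper_metric = "mahalanobis", caliper = 1000)

  # oracle: exhaustive Mahalanobis distances on the same matrix
  X <- conf[, , drop = FALSE]
  Sinv <- solve(cov(X) + diag(1e-8, 2))
  for (s in m$strata) {
    i <- s$exposed_idx
    cand <- which(co$exposure == 0)
    d <- apply(X[cand, ], 1, function(r) {
      v <- r - X[i, ]; sqrt(v %*% Sinv %*% v)
    })
    oracle <- co$patient_id[cand[order(d)][1:5]]
    expect_setequal(s$matched_unexposed_ids, oracle)
  }
})

test_that("cmh_test reproduces the Mantel-Haenszel formulas and mantelhaen.test", {
  # single stratum: the crude cross-product ratio
  one <- cmh_test(contingency_table(10, 10, 10, 10))
  expect_equal(one$or_point, 1)
  # hand-computed MH OR for two strata
  two <- cmh_test(list(contingency_table(4, 1, 2, 3), contingency_table(2, 3, 1, 4)))
  expect_equal(two$or_point, (4 * 3 / 10 + 2 * 4 / 10) / (1 * 2 / 10 + 3 * 1 / 10),
               tolerance = 1e-12)

  # stratification invariance for homogeneous tables
  t1 <- contingency_table(8, 12, 15, 25)
  expect_equal(cmh_test(list(t1, t1))$or_point, cmh_test(t1)$or_point,
               tolerance = 1e-12)

  # single stratum agrees with ad/(bc), and doubling all cells leaves it fixed
  set.seed(50)
  for (i in 1:10) {
    tb <- rand_table()
    expect_equal(cmh_test(tb)$or_point, tb$a * tb$d / (tb$b * tb$c),
                 tolerance = 1e-12)
    tb2 <- contingency_table(2 * tb$a, 2 * tb$b, 2 * tb$c, 2 * tb$d)
    expect_equal(cmh_test(tb2)$or_point, cmh_test(tb)$or_point, tolerance = 1e-12)
  }

  # independent cross-check: OR, RBG CI, and chi-square against mantelhaen.test
  set.seed(51)
  tabs <- replicate(4, rand_table(), simplify = FALSE)
  est <- cmh_test(tabs)
  arr <- array(unlist(lapply(tabs, function(t) c(t$a, t$c, t$b, t$d))),
               dim = c(2, 2, 4))
  mh <- mantelhaen.test(arr, correct = FALSE)
  expect_equal(est$or_point, unname(mh$estimate), tolerance = 1e-10)
  expect_equal(est$ci95, as.numeric(mh$conf.int), tolerance = 1e-4)
  expect_equal(est$extra$cmh_chisq, unname(mh$statistic), tolerance = 1e-10)

  # degenerate strata contribute nothing; all-degenerate errors
  empty <- contingency_table(0, 10, 0, 10)
  expect_equal(cmh_test(list(t1, empty))$or_point, cmh_test(t1)$or_point)
  expect_error(cmh_test(list(empty)), "degenerate")
})

test_that("covariate_balance measures and ATT weighting improves it", {
  set.seed(60)
  n <- 3000
  x <- rnorm(n)
  e <- rbinom(n, 1, plogis(0.8 * x))
  X <- cbind(conf_x1 = x, conf_x2 = rnorm(n))
  bal0 <- covariate_balance(X, e)
  expect_equal(bal0$smd_unweighted, bal0$smd_weighted) # unit weights reduce
  expect_gt(abs(bal0$smd_unweighted[1]), 0.3)

  w <- ifelse(e == 1, 1, plogis(0.8 * x) / (1 - plogis(0.8 * x)))
  bal1 <- covariate_balance(X, e, w)
  expect_lt(abs(bal1$smd_weighted[1]), abs(bal1$smd_unweighted[1]))
  expect_lt(abs(bal1$smd_weighted[1]), 0.1)

  # identical distributions give SMD ~ 0; constant covariate warns and gives 0
  Xnull <- cbind(conf_a = rnorm(n))
  enull <- rbinom(n, 1, 0.5)
  expect_lt(abs(covariate_balance(Xnull, enull)$smd_unweighted[1]), 0.1)
  w <- capture_warnings(b <- covariate_balance(cbind(conf_c = rep(1, n)), enull))
  expect_true(any(grepl("zero pooled SD", w)))
  expect_identical(b$smd_unweighted, 0)
})

test_that("adjusted estimation reduces confounding bias on the synthetic DGP", {
  cfg <- dgp_config(n_patients = 8000)
  ora <- true_marginal_effect(cfg, n_mc = 2e5, seed = 77)
  src <- generate_source(cfg, cfg$dialects$optum, seed = 78)
  co <- build_cohort(src, cohort_spec("ARD"))
  tab <- cohort_table(co, "outcome_ventilation")
  crude <- log(tab$a * tab$d / (tab$b * tab$c))
  X <- confounder_matrix(co)
  ps <- fit_propensity(X, co$exposure, seed = 79)
  tr <- trim_overlap(ps, co$exposure)
  k <- tr$keep
  adj <- ipw_logistic(X[k, , drop = FALSE], co$exposure[k],
                      co$outcome_ventilation[k], tr$scores[k])
  expect_lt(abs(adj$log_or - log(ora$marginal_or)),
            abs(crude - log(ora$marginal_or)))
})
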