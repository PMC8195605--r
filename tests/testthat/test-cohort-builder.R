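index <- as.Date("2010-12-01")

test_that("compute_mpr follows the truncated-supply definition", {
  expect_equal(compute_mpr(NULL, index), 0, ignore_attr = TRUE)
  expect_false(attr(compute_mpr(NULL, index), "any_use"))

  # one 183-day fill entirely inside the window: 183/365, exposed at 0.5
  f <- fill_row("p", index - 200, days = 183L)
  m <- compute_mpr(f, index)
  expect_equal(as.numeric(m), 183 / 365)
  expect_identical(classify_exposure(m, threshold = 0.5), "exposed")

  # saturation
  expect_equal(as.numeric(compute_mpr(fill_row("p", index - 365, days = 365L), index)), 1)

  # supply overlapping the index date is truncated at the index date
  expect_equal(as.numeric(compute_mpr(fill_row("p", index - 100, days = 200L), index)),
               100 / 365)

  # fills on/after index, outside the window, or for other drugs are ignored
  f2 <- rbind(fill_row("p", index, days = 90L),
              fill_row("p", index - 400, days = 90L),
              fill_row("p", index - 50, days = 10L, drug = "metformin"))
  expect_equal(as.numeric(compute_mpr(f2, index)), 0)

  # drug-specific filter
  f3 <- rbind(fill_row("p", index - 100, days = 50L, drug = "doxazosin"),
              fill_row("p", index - 100, days = 50L, drug = "tamsulosin"))
  expect_equal(as.numeric(compute_mpr(f3, index, drug_filter = "tamsulosin")), 50 / 365)
  expect_equal(as.numeric(compute_mpr(f3, index)), 100 / 365)
})

test_that("exposure classification is a strict trichotomy", {
  expect_identical(classify_exposure(0, FALSE), "unexposed")
  expect_identical(classify_exposure(0.25, TRUE), "excluded")
  expect_identical(classify_exposure(0.50, TRUE), "exposed")  # boundary inclusive
  expect_error(classify_exposure(0.2, FALSE), "inconsistent")
  # exhaustive and mutually exclusive over random histories
  set.seed(1)
  mpr <- c(0, runif(200, 0, 1.4))
  use <- mpr > 0
  cls <- classify_exposure(mpr, use)
  expect_true(all(cls %in% c("exposed", "unexposed", "excluded")))
  expect_identical(cls == "exposed", mpr >= 0.5)
  expect_identical(cls == "unexposed", !use)
})

test_that("find_index_admission picks the first qualifying admission within calendar windows", {
  sp <- cohort_spec("ARD")
  win <- list(c(2004, 2015), c(2018, 2019))
  expect_null(find_index_admission(adm_row("p", "2010-05-01")[0, ], sp, win))

  two <- rbind(adm_row("p", "2014-03-01"), adm_row("p", "2010-05-01"))
  hit <- find_index_admission(two, sp, win)
  expect_equal(hit$admit_date, as.Date("2010-05-01"))

  # admissions only in the excluded ICD-transition years yield none
  gap <- adm_row("p", "2017-06-01", codes = "R0603")
  expect_null(find_index_admission(gap, sp, win))
  # non-matching codes yield none
  expect_null(find_index_admission(adm_row("p", "2010-05-01", codes = "486"), sp, win))
})

test_that("derive_outcomes respects the ventilation requirement and death dialects", {
  flag <- test_dialect("in_hospital_flag")
  month <- test_dialect("death_month_within_1_month")

  # death without ventilation is not the composite outcome
  a <- adm_row("p", "2010-05-20", died = 1L)
  expect_equal(derive_outcomes(list(), a, flag),
               c(ventilation = 0L, vent_death = 0L))

  av <- adm_row("p", "2010-05-20", proc = "9670")
  expect_equal(derive_outcomes(list(), av, flag),
               c(ventilation = 1L, vent_death = 0L))
  avd <- adm_row("p", "2010-05-20", proc = "9670", died = 1L)
  expect_equal(derive_outcomes(list(), avd, flag),
               c(ventilation = 1L, vent_death = 1L))

  # month dialect: death month within one month of the admission month
  for (case in list(list("2010-05-25", 1L), list("2010-06-28", 1L),
                    list("2010-07-01", 0L), list("2010-04-30", 0L))) {
    rec <- list(death_date = as.Date(case[[1]]))
    expect_equal(unname(derive_outcomes(rec, av, month)["vent_death"]), case[[2]])
  }
  expect_equal(unname(derive_outcomes(list(), av, month)["vent_death"]), 0L)
})

test_that("build_cohort applies staged exclusions with consistent CONSORT accounting", {
  pts <- rbind(patient_row("a", birth_year = 1950),
               patient_row("b", birth_year = 1950, sex = "female"),
               patient_row("c", birth_year = 1980),          # age 30 at index
               patient_row("d", birth_year = 1950,
                           enroll_start = as.Date("2010-10-01")), # short enrollment
               patient_row("e", birth_year = 1950),          # partial user
               patient_row("f", birth_year = 1950))          # no admission
  adm <- rbind(adm_row("a", "2010-12-01"), adm_row("b", "2010-12-01"),
               adm_row("c", "2010-12-01"), adm_row("d", "2010-12-01"),
               adm_row("e", "2010-12-01"))
  fills <- rbind(fill_row("a", "2010-06-01", days = 200L),
                 fill_row("e", "2010-10-01", days = 60L))
  src <- manual_source(pts, fills = fills, admissions = adm)
  co <- build_cohort(src, cohort_spec("ARD"))

  expect_identical(nrow(co), 1L)
  expect_identical(co$patient_id, "a")
  expect_identical(co$exposure, 1L)
  flow <- attr(co, "consort")$stages
  expect_identical(flow$n_remaining, c(6L, 5L, 4L, 3L, 2L, 1L))
  expect_identical(sum(flow$n_excluded), 5L)
  # bookkeeping identity: final CONSORT n equals the number of cohort rows
  expect_identical(flow$n_remaining[nrow(flow)], nrow(co))
})

test_that("an all-female source yields an empty cohort flagged at the sex stage", {
  pts <- rbind(patient_row("a", sex = "female"), patient_row("b", sex = "female"))
  src <- manual_source(pts, admissions = adm_row("a", "2010-12-01"))
  expect_warning(co <- build_cohort(src, cohort_spec("ARD")), "empty eligible cohort")
  expect_identical(nrow(co), 0L)
  flow <- attr(co, "consort")$stages
  expect_identical(flow$n_excluded[flow$stage == "male sex"], 2L)
})

test_that("standardized confounders have mean 0 and unit variance cohort-wide", {
  cfg <- dgp_config(n_patients = 3000)
  src <- generate_source(cfg, cfg$dialects$marketscan, seed = 17)
  co <- build_cohort(src, cohort_spec("ARD"))
  X <- confounder_matrix(co)
  nontrivial <- apply(X, 2, function(v) length(unique(v)) > 1)
  expect_lt(max(abs(colMeans(X[, nontrivial]))), 1e-8)
  expect_lt(max(abs(apply(X[, nontrivial], 2, var) - 1)), 1e-8)
})

test_that("derived comorbidity flags and exposure match the generator's plants", {
  cfg <- dgp_config(n_patients = 4000)
  src <- generate_source(cfg, cfg$dialects$optum, seed = 23)
  co <- build_cohort(src, cohort_spec("ARD"))
  tr <- src$truth[match(co$patient_id, src$truth$patient_id)]
  expect_identical(co$exposure, as.integer(tr$exposure_class == "exposed"))
  expect_identical(co$outcome_ventilation, tr$ventilation)
  expect_identical(co$outcome_vent_death,
                   as.integer(tr$ventilation & tr$death_with_vent))
})

test_that("planted partial users are exactly the exposure-stage exclusions", {
  cfg <- dgp_config(n_patients = 5000)
  win <- cfg$dialects$optum$icd_era_windows
  src <- generate_source(cfg, cfg$dialects$optum, seed = 29)
  co <- build_cohort(src, cohort_spec("ARD"))
  tr <- src$truth
  survivors <- !tr$short_enrollment &
    sapply(tr$index_year, function(y) any(sapply(win, function(w) y >= w[1] & y <= w[2])))
  expected <- sum(tr$exposure_class == "partial" & survivors)
  flow <- attr(co, "consort")$stages
  got <- flow$n_excluded[grepl("exposure classification", flow$stage)]
  expect_identical(got, expected)
})

test_that("index admission is minimal and calendar windows act monotonically", {
  # earlier qualifying admission wins
  pts <- patient_row("a")
  adm <- rbind(adm_row("a", "2012-07-01"), adm_row("a", "2008-03-01"))
  co <- build_cohort(manual_source(pts, admissions = adm), cohort_spec("ARD"))
  expect_equal(co$index_date, as.Date("2008-03-01"))

  # enlarging the calendar windows never shrinks the cohort
  cfg <- dgp_config(n_patients = 2000)
  src <- generate_source(cfg, cfg$dialects$marketscan, seed = 31)
  narrow <- build_cohort(src, cohort_spec("ARD", calendar_windows = list(c(2004, 2010))))
  wide <- build_cohort(src, cohort_spec("ARD", calendar_windows = list(c(2004, 2016))))
  wider <- build_cohort(src, cohort_spec("ARD", calendar_windows = list(c(2004, 2019))))
  expect_lte(nrow(narrow), nrow(wide))
  expect_lte(nrow(wide), nrow(wider))
  expect_true(all(narrow$patient_id %in% wide$patient_id))
})

test_that("consort_flow rejects inconsistent accounting", {
  bad <- data.frame(stage = c("all", "s1"), n_remaining = c(10L, 12L),
                    n_excluded = c(0L, 2L))
  expect_error(consort_flow(bad), "consort validation error")
  bad2 <- data.frame(stage = c("all", "s1"), n_remaining = c(10L, 7L),
                     n_excluded = c(0L, 2L))
  expect_error(consort_flow(bad2), "reconcile")
})
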