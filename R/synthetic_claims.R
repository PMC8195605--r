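#' Describe one claims source's coding dialect
#'
#' Real claims warehouses differ in ways that matter for cohort construction:
#' the age range they cover (employer-sponsored databases stop at Medicare
#' age 65), how death is coded (an in-hospital discharge flag versus a death
#' month from an external registry), and which calendar years carry usable
#' diagnosis codes for the index condition (the ICD-9 to ICD-10 transition
#' leaves gaps). A `source_dialect` bundles those conventions.
#'
#' @param name Source label, e.g. `"marketscan"`.
#' @param age_range Length-2 integer vector within \[45, 85\].
#' @param death_coding Either `"in_hospital_flag"` (death observable only as a
#'   flag on the inpatient discharge record) or `"death_month_within_1_month"`
#'   (death observable as a calendar month from a registry; the outcome rule
#'   asks whether the death month is within one month of the admission month).
#' @param icd_era_windows List of `c(start_year, end_year)` intervals during
#'   which index admissions are codable for this source.
#' @return A `source_dialect` object.
#' @export
#' @examples
#' source_dialect("optum", c(45, 85), "death_month_within_1_month",
#'                list(c(2004, 2015), c(2018, 2019)))
source_dialect <- function(name, age_range,
                           death_coding = c("in_hospital_flag",
                                            "death_month_within_1_month"),
                           icd_era_windows) {
  death_coding <- match.arg(death_coding)
  stopifnot(is.character(name), length(age_range) == 2L,
            age_range[1] < age_range[2],
            age_range[1] >= 45, age_range[2] <= 85,
            is.list(icd_era_windows), length(icd_era_windows) >= 1L)
  for (w in icd_era_windows) stopifnot(length(w) == 2L, w[1] <= w[2])
  structure(list(name = name, age_range = as.integer(age_range),
                 death_coding = death_coding,
                 icd_era_windows = lapply(icd_era_windows, as.integer)),
            class = "source_dialect")
}

#' @rdname source_dialect
#' @export
default_dialects <- function() {
  list(
    marketscan = source_dialect("marketscan", c(45, 65), "in_hospital_flag",
                                list(c(2004, 2016))),
    optum = source_dialect("optum", c(45, 85), "death_month_within_1_month",
                           list(c(2004, 2015), c(2018, 2019)))
  )
}

#' Configure the synthetic claims data-generating process
#'
#' The generator emulates the structure of multi-source administrative claims
#' for older men admitted with an acute respiratory condition: exposure to an
#' alpha-1-AR antagonist arises from a logistic model on age and comorbidity
#' burden (confounding by indication), ventilation arises from a logistic
#' model with a known conditional log odds ratio on exposure, and death is
#' drawn conditionally on ventilation so the composite
#' ventilation-and-death outcome is well defined.
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 20,000 patients per source, a protective conditional OR of 0.70 on
#' ventilation, moderate confounding, a 10% baseline ventilation rate among
#' the unexposed, and 15% exposure prevalence.
#'
#' @param n_patients Patients per source.
#' @param true_log_or Conditional log odds ratio of exposure on ventilation.
#' @param confounding_strength Nonnegative scale of the shared association of
#'   age/comorbidity burden with both exposure and outcome; 0 gives a
#'   randomized exposure.
#' @param baseline_outcome_rate Ventilation probability in the unexposed arm,
#'   strictly inside (0, 1).
#' @param exposure_prevalence_target Marginal exposure probability, strictly
#'   inside (0, 1).
#' @param partial_user_rate Fraction of otherwise-unexposed patients planted
#'   with partial drug use (0 < MPR < threshold); these are excluded at the
#'   exposure stage by design and exercise the trichotomy.
#' @param death_given_vent Probability of death given ventilation (unexposed).
#' @param true_log_or_death Conditional log OR of exposure on death given
#'   ventilation (0 by default; the composite effect then flows through
#'   ventilation alone).
#' @param diagnosis Index condition coded on every index admission.
#' @param seed Default seed used when `generate_source()` is not given one.
#' @param dialects Named list of [source_dialect()] objects.
#' @return A `dgp_config` object.
#' @export
dgp_config <- function(n_patients = 20000,
                       true_log_or = log(0.70),
                       confounding_strength = 0.5,
                       baseline_outcome_rate = 0.10,
                       exposure_prevalence_target = 0.15,
                       partial_user_rate = 0.04,
                       death_given_vent = 0.45,
                       true_log_or_death = 0,
                       diagnosis = c("ARD", "pneumonia"),
                       seed = 1L,
                       dialects = default_dialects()) {
  diagnosis <- match.arg(diagnosis)
  for (p in c(baseline_outcome_rate, exposure_prevalence_target,
              death_given_vent)) {
    if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
      stop("configuration error: probability parameters must lie strictly inside (0, 1)")
    }
  }
  if (partial_user_rate < 0 || partial_user_rate >= 1) {
    stop("configuration error: partial_user_rate must lie in [0, 1)")
  }
  if (confounding_strength < 0) stop("configuration error: confounding_strength must be >= 0")
  stopifnot(n_patients >= 1, length(dialects) >= 1)
  if (!all(vapply(dialects, inherits, logical(1), "source_dialect"))) {
    stop("configuration error: dialects must be source_dialect objects")
  }
  structure(list(n_patients = as.integer(n_patients), true_log_or = true_log_or,
                 confounding_strength = confounding_strength,
                 baseline_outcome_rate = baseline_outcome_rate,
                 exposure_prevalence_target = exposure_prevalence_target,
                 partial_user_rate = partial_user_rate,
                 death_given_vent = death_given_vent,
                 true_log_or_death = true_log_or_death,
                 diagnosis = diagnosis, seed = as.integer(seed),
                 dialects = dialects),
            class = "dgp_config")
}

# z-score that degrades gracefully on constant input
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Shared latent structure: age, seven comorbidity flags with age-dependent
# prevalence, a latent frailty, and the standardized confounder score that
# drives both exposure and outcome. Assumes the RNG is already seeded.
simulate_latents <- function(n, dialect) {
  ages <- sample(seq(dialect$age_range[1], dialect$age_range[2]), n, replace = TRUE)
  z_age <- zscore(ages)
  base_prev <- c(hypertension = 0.45, ischemic_heart_disease = 0.15,
                 acute_mi = 0.05, heart_failure = 0.08, copd = 0.12,
                 diabetes = 0.20, cancer = 0.10)
  como <- vapply(base_prev, function(b) {
    rbinom(n, 1L, plogis(qlogis(b) + 0.5 * (ages - 65) / 10))
  }, integer(n))
  if (n == 1L) como <- matrix(como, nrow = 1, dimnames = list(NULL, names(base_prev)))
  frailty <- rnorm(n, 0, 0.5)
  burden <- as.numeric(como %*% c(1, 1, 1.5, 1.5, 1.2, 1, 1)) + frailty
  z_burden <- zscore(burden)
  list(age = ages, z_age = z_age, como = como, z_burden = z_burden,
       conf_score = 0.6 * z_age + 0.4 * z_burden)
}

# Solve the logistic intercept so that mean(plogis(a + offset)) == target.
calibrate_intercept <- function(target, offset) {
  uniroot(function(a) mean(plogis(a + offset)) - target,
          interval = c(-25, 25), tol = 1e-10)$root
}

era_icd9 <- function(year) year <= 2016

#' Generate one synthetic claims source
#'
#' Emits a full claims-shaped source: patients, prescription fills, inpatient
#' admissions (with diagnosis/procedure codes and, under the flag dialect, an
#' in-hospital death flag), outpatient visits carrying comorbidity codes, and
#' a death table (month dialect only). Every patient receives an index
#' admission for the configured diagnosis in a uniformly drawn calendar year
#' 2004--2019; the source's `icd_era_windows` then governs which of those are
#' codable downstream. Exposed patients are given monthly 30-day fills
#' covering at least 7 of the prior 12 months (MPR > 0.5); planted partial
#' users receive 2--5 months of supply; unexposed patients receive none.
#'
#' Identical `(config, dialect, seed)` inputs give identical output. The
#' returned object carries a `truth` table (potential-outcome probabilities
#' and the planted exposure class per patient) for parameter-recovery tests;
#' `truth` is never written to disk by [write_claims_tables()].
#'
#' @param config A [dgp_config()].
#' @param dialect A [source_dialect()]; must be one of `config$dialects`.
#' @param seed Integer seed for this source.
#' @return A `claims_source` object: list of data.tables `patients`, `fills`,
#'   `admissions`, `visits`, `deaths`, plus `dialect` and `truth`.
#' @export
generate_source <- function(config, dialect, seed = config$seed) {
  stopifnot(inherits(config, "dgp_config"), inherits(dialect, "source_dialect"))
  if (!dialect$name %in% vapply(config$dialects, `[[`, character(1), "name")) {
    stop("configuration error: dialect '", dialect$name, "' is not in config$dialects")
  }
  n <- config$n_patients
  cs <- config$confounding_strength
  with_seed(seed, {
    L <- simulate_latents(n, dialect)

    ## exposure: logistic on the confounder score, intercept calibrated to the
    ## target prevalence on this sample
    a0 <- calibrate_intercept(config$exposure_prevalence_target, cs * L$conf_score)
    p_exposure <- plogis(a0 + cs * L$conf_score)
    exposed <- rbinom(n, 1L, p_exposure) == 1L
    partial <- !exposed & runif(n) < config$partial_user_rate
    exposure_class <- ifelse(exposed, "exposed", ifelse(partial, "partial", "unexposed"))

    ## index admission date and length of stay
    index_year <- sample(2004:2019, n, replace = TRUE)
    index_date <- as.Date(sprintf("%d-01-01", index_year)) +
      (sample.int(365L, n, replace = TRUE) - 1L)
    los <- 1L + rpois(n, 4)

    ## potential outcomes: ventilation, then death given ventilation
    g0 <- calibrate_intercept(config$baseline_outcome_rate, cs * L$conf_score)
    p_vent1 <- plogis(g0 + config$true_log_or + cs * L$conf_score)
    p_vent0 <- plogis(g0 + cs * L$conf_score)
    u_vent <- runif(n)
    vent <- ifelse(exposed, u_vent < p_vent1, u_vent < p_vent0)
    d0 <- calibrate_intercept(config$death_given_vent, 0.3 * L$z_age)
    p_death1 <- plogis(d0 + config$true_log_or_death + 0.3 * L$z_age)
    p_death0 <- plogis(d0 + 0.3 * L$z_age)
    u_death <- runif(n)
    death_iv <- vent & ifelse(exposed, u_death < p_death1, u_death < p_death0)
    late_death <- !death_iv & runif(n) < 0.02

    ## enrollment; a small fraction lack the 12-month pre-index lookback
    short_enroll <- runif(n) < 0.05
    lookback <- ifelse(short_enroll, runif(n, 120, 330), runif(n, 430, 2200))
    enroll_start <- index_date - floor(lookback)
    enroll_end <- index_date + los + sample(30:120, n, replace = TRUE)

    patient_id <- sprintf("%s-%06d", dialect$name, seq_len(n))
    patients <- data.table(
      patient_id = patient_id, sex = "male",
      birth_year = index_year - L$age,
      enroll_start = enroll_start, enroll_end = enroll_end
    )

    ## -- fills ---------------------------------------------------------------
    drug_sub <- sample(c("tamsulosin", "doxazosin", "alfuzosin"), n,
                       replace = TRUE, prob = c(0.65, 0.25, 0.10))
    fills_for <- function(idx, k_range) {
      if (!length(idx)) return(NULL)
      k <- sample(k_range, length(idx), replace = TRUE)
      data.table(
        patient_id = rep(patient_id[idx], k),
        drug_code = rep(drug_sub[idx], k),
        fill_date = pmax(rep(index_date[idx], k) - 30L * sequence(k),
                         rep(enroll_start[idx], k)),
        days_supplied = 30L
      )
    }
    nf <- rpois(n, 1.5)
    noise_fills <- if (sum(nf) > 0) data.table(
      patient_id = rep(patient_id, nf),
      drug_code = sample(noise_drug_codes(), sum(nf), replace = TRUE),
      fill_date = rep(index_date, nf) -
        floor(runif(sum(nf)) * pmin(rep(as.numeric(index_date - enroll_start), nf), 900)),
      days_supplied = sample(c(30L, 90L), sum(nf), replace = TRUE)
    ) else NULL
    fills <- rbindlist(list(fills_for(which(exposed), 7:12),
                            fills_for(which(partial), 2:5),
                            noise_fills))
    if (is.null(fills) || nrow(fills) == 0) {
      fills <- data.table(patient_id = character(), drug_code = character(),
                          fill_date = as.Date(character()), days_supplied = integer())
    }

    ## -- admissions ----------------------------------------------------------
    diag_codes <- diagnosis_codesets()[[config$diagnosis]]
    vent_code9 <- c("9670", "9671", "9672")
    vent_code10 <- c("5A1935Z", "5A1945Z", "5A1955Z")
    icd9 <- era_icd9(index_year)
    index_adm <- data.table(
      patient_id = patient_id,
      admit_date = index_date,
      discharge_date = index_date + los,
      diagnosis_codes = ifelse(icd9, diag_codes[1], diag_codes[2]),
      procedure_codes = ifelse(vent,
                               ifelse(icd9, sample(vent_code9, n, replace = TRUE),
                                      sample(vent_code10, n, replace = TRUE)), ""),
      died_in_hospital = as.integer(dialect$death_coding == "in_hospital_flag" & death_iv)
    )
    npr <- pmin(rnbinom(n, size = 0.6, mu = exp(log(0.25) + 0.5 * L$z_burden)), 5L)
    prior_adm <- if (sum(npr) > 0) {
      pid <- rep(patient_id, npr)
      adm <- rep(index_date, npr) - sample(20:365, sum(npr), replace = TRUE)
      adm <- pmax(adm, rep(enroll_start, npr))
      plos <- 1L + rpois(sum(npr), 1.5)
      data.table(
        patient_id = pid, admit_date = adm,
        discharge_date = pmin(adm + plos, rep(index_date, npr) - 1L),
        diagnosis_codes = ifelse(rep(icd9, npr), "V70.0", "Z0000"),
        procedure_codes = "", died_in_hospital = 0L
      )
    } else NULL
    admissions <- rbindlist(list(index_adm, prior_adm))

    ## -- outpatient visits (carry comorbidity codes) -------------------------
    nv <- pmin(rnbinom(n, size = 1.2, mu = exp(log(5) + 0.3 * L$z_burden)), 40L)
    plain_visits <- if (sum(nv) > 0) data.table(
      patient_id = rep(patient_id, nv),
      visit_date = pmax(rep(index_date, nv) - sample.int(365L, sum(nv), replace = TRUE),
                        rep(enroll_start, nv)),
      diagnosis_codes = ""
    ) else NULL
    como_sets <- comorbidity_codesets()
    como_visits <- lapply(colnames(L$como), function(cm) {
      idx <- which(L$como[, cm] == 1L)
      if (!length(idx)) return(NULL)
      data.table(
        patient_id = patient_id[idx],
        visit_date = pmax(index_date[idx] - sample(30:360, length(idx), replace = TRUE),
                          enroll_start[idx]),
        diagnosis_codes = ifelse(icd9[idx], como_sets[[cm]][1], como_sets[[cm]][2])
      )
    })
    visits <- rbindlist(c(list(plain_visits), como_visits))
    if (is.null(visits) || nrow(visits) == 0) {
      visits <- data.table(patient_id = character(), visit_date = as.Date(character()),
                           diagnosis_codes = character())
    }

    ## -- deaths --------------------------------------------------------------
    ## Day resolution internally; the month dialect coarsens at write time.
    ## Under the flag dialect only in-hospital deaths are observable (as the
    ## admission flag); post-discharge deaths are unrecorded, as in claims.
    deaths <- if (dialect$death_coding == "death_month_within_1_month") {
      dd_iv <- which(death_iv)
      dd_late <- which(late_death)
      data.table(
        patient_id = c(patient_id[dd_iv], patient_id[dd_late]),
        death_date = c(index_date[dd_iv] + los[dd_iv],
                       index_date[dd_late] + los[dd_late] +
                         sample(75:400, length(dd_late), replace = TRUE))
      )
    } else {
      data.table(patient_id = character(), death_date = as.Date(character()))
    }

    truth <- data.table(
      patient_id = patient_id, exposure_class = exposure_class, age = L$age,
      p_exposure = p_exposure, p_vent_exposed = p_vent1, p_vent_unexposed = p_vent0,
      ventilation = as.integer(vent), death_with_vent = as.integer(death_iv),
      index_year = index_year, short_enrollment = short_enroll
    )

    structure(list(source = dialect$name, dialect = dialect,
                   patients = patients, fills = fills, admissions = admissions,
                   visits = visits, deaths = deaths, truth = truth),
              class = "claims_source")
  })
}

#' @export
print.claims_source <- function(x, ...) {
  cat("<claims_source>", x$source, "\n")
  cat("  patients:", nrow(x$patients),
      "| fills:", nrow(x$fills),
      "| admissions:", nrow(x$admissions),
      "| visits:", nrow(x$visits),
      "| deaths:", nrow(x$deaths), "\n")
  cat("  death coding:", x$dialect$death_coding, "\n")
  invisible(x)
}

#' Population marginal effect implied by a DGP configuration
#'
#' Monte-Carlo oracle for parameter-recovery tests: simulates the latent
#' covariates for `n_mc` patients (split equally over the configured
#' dialects), evaluates both potential-outcome probabilities for every
#' patient, and averages them into marginal risks. Because the logistic
#' outcome model is noncollapsible, the marginal OR generally differs from
#' `exp(true_log_or)`; the gap closes as the baseline rate tends to zero.
#'
#' @param config A [dgp_config()].
#' @param n_mc Number of Monte-Carlo patients, at least 1e5.
#' @param seed Integer seed.
#' @return A `marginal_effect` list: `marginal_or` and `marginal_rrr` for the
#'   ventilation outcome, a `vent_death` sublist for the composite outcome,
#'   and the marginal risks `p1`, `p0` under exposure/no exposure.
#' @export
true_marginal_effect <- function(config, n_mc = 1e5, seed = config$seed) {
  stopifnot(inherits(config, "dgp_config"))
  if (n_mc < 1e5) stop("n_mc must be at least 1e5 for a stable oracle")
  cs <- config$confounding_strength
  nd <- ceiling(n_mc / length(config$dialects))
  acc <- with_seed(seed, lapply(config$dialects, function(dialect) {
    L <- simulate_latents(nd, dialect)
    g0 <- calibrate_intercept(config$baseline_outcome_rate, cs * L$conf_score)
    p_vent1 <- plogis(g0 + config$true_log_or + cs * L$conf_score)
    p_vent0 <- plogis(g0 + cs * L$conf_score)
    d0 <- calibrate_intercept(config$death_given_vent, 0.3 * L$z_age)
    p_d1 <- plogis(d0 + config$true_log_or_death + 0.3 * L$z_age)
    p_d0 <- plogis(d0 + 0.3 * L$z_age)
    cbind(p_vent1, p_vent0, pcd1 = p_vent1 * p_d1, pcd0 = p_vent0 * p_d0)
  }))
  m <- colMeans(do.call(rbind, acc))
  or_of <- function(p1, p0) (p1 / (1 - p1)) / (p0 / (1 - p0))
  structure(list(
    marginal_or = or_of(m["p_vent1"], m["p_vent0"]),
    marginal_rrr = 1 - m["p_vent1"] / m["p_vent0"],
    p1 = unname(m["p_vent1"]), p0 = unname(m["p_vent0"]),
    vent_death = list(
      marginal_or = or_of(m["pcd1"], m["pcd0"]),
      marginal_rrr = 1 - m["pcd1"] / m["pcd0"],
      p1 = unname(m["pcd1"]), p0 = unname(m["pcd0"])
    ),
    n_mc = length(config$dialects) * nd
  ), class = "marginal_effect")
}

#' Write and read the delimited claims schema
#'
#' Five comma-separated tables with header rows and ISO-8601 dates:
#' `patients.csv` (patient_id, sex, birth_year, enroll_start, enroll_end),
#' `fills.csv` (patient_id, drug_code, fill_date, days_supplied),
#' `admissions.csv` (patient_id, admit_date, discharge_date, diagnosis_codes,
#' procedure_codes, died_in_hospital), `visits.csv` (patient_id, visit_date,
#' diagnosis_codes) and `deaths.csv` (patient_id, death_date). Multiple codes
#' in one field are `;`-joined. Row order is never significant. Under the
#' `death_month_within_1_month` dialect, death dates are coarsened to the
#' first of the month at write time; all other dates keep day resolution.
#' The in-memory `truth` table is never written.
#'
#' @param records A `claims_source`.
#' @param directory Output directory, created if needed.
#' @return `write_claims_tables()`: invisibly, the vector of file paths.
#'   `read_claims_tables()`: a `claims_source` (with `truth = NULL`).
#' @export
write_claims_tables <- function(records, directory) {
  stopifnot(inherits(records, "claims_source"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) stop("cannot create directory: ", directory)
  }
  deaths <- copy(records$deaths)
  if (records$dialect$death_coding == "death_month_within_1_month" && nrow(deaths)) {
    deaths[, death_date := as.Date(format(death_date, "%Y-%m-01"))]
  }
  tables <- list(patients = records$patients, fills = records$fills,
                 admissions = records$admissions, visits = records$visits,
                 deaths = deaths)
  paths <- file.path(directory, paste0(names(tables), ".csv"))
  for (i in seq_along(tables)) {
    res <- tryCatch(fwrite(tables[[i]], paths[i], dateTimeAs = "ISO"),
                    error = function(e) e)
    if (inherits(res, "error")) {
      stop("failed to write ", paths[i], ": ", conditionMessage(res))
    }
  }
  invisible(paths)
}

#' @rdname write_claims_tables
#' @param dialect The [source_dialect()] the tables were written under; needed
#'   to interpret the death coding.
#' @export
read_claims_tables <- function(directory, dialect) {
  stopifnot(dir.exists(directory), inherits(dialect, "source_dialect"))
  rd <- function(name, date_cols, int_cols = character()) {
    path <- file.path(directory, paste0(name, ".csv"))
    if (!file.exists(path)) stop("missing claims table file: ", path)
    dt <- fread(path, colClasses = "character")
    for (dc in date_cols) if (dc %in% names(dt)) dt[[dc]] <- as.Date(dt[[dc]])
    for (ic in int_cols) if (ic %in% names(dt)) dt[[ic]] <- as.integer(dt[[ic]])
    dt
  }
  structure(list(
    source = dialect$name, dialect = dialect,
    patients = rd("patients", c("enroll_start", "enroll_end"), "birth_year"),
    fills = rd("fills", "fill_date", "days_supplied"),
    admissions = rd("admissions", c("admit_date", "discharge_date"), "died_in_hospital"),
    visits = rd("visits", "visit_date"),
    deaths = rd("deaths", "death_date"),
    truth = NULL
  ), class = "claims_source")
}
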