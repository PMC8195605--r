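#' Specify cohort inclusion, exposure, confounder and outcome rules
#'
#' @param diagnosis Index condition: `"ARD"` (acute respiratory distress) or
#'   `"pneumonia"`.
#' @param codeset Diagnosis codes identifying the index admission; defaults to
#'   the representative set in [diagnosis_codesets()]. A plain-text file of
#'   one code per line may be supplied via [read_codeset()].
#' @param age_range Inclusive age limits at index, within \[45, 85\].
#' @param exposure_drug `"any_alpha_blocker"`, a single drug code such as
#'   `"tamsulosin"` or `"doxazosin"`, or a character vector of codes.
#' @param mpr_window_days Lookback over which the medication possession ratio
#'   (MPR) is computed; 365 by default, 90 for the short-window sensitivity
#'   variant.
#' @param mpr_threshold Exposure threshold on the MPR, in (0, 1\]; the default
#'   0.5 is the "supply covering six of the last 12 months" rule.
#' @param calendar_windows Optional list of `c(start_year, end_year)` windows
#'   for admissible index years; defaults to the source dialect's
#'   `icd_era_windows`.
#' @param outcome_set Outcomes to derive: any of `"ventilation"`,
#'   `"vent_death"`, `"death"` (the death-only registry variant).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(diagnosis = c("ARD", "pneumonia"), codeset = NULL,
                        age_range = c(45, 85),
                        exposure_drug = "any_alpha_blocker",
                        mpr_window_days = 365, mpr_threshold = 0.5,
                        calendar_windows = NULL,
                        outcome_set = c("ventilation", "vent_death")) {
  diagnosis <- match.arg(diagnosis)
  if (is.null(codeset)) codeset <- diagnosis_codesets()[[diagnosis]]
  stopifnot(length(age_range) == 2L, age_range[1] >= 45, age_range[2] <= 85,
            age_range[1] < age_range[2], mpr_window_days > 0)
  if (mpr_threshold <= 0 || mpr_threshold > 1) {
    stop("mpr_threshold must lie in (0, 1]")
  }
  outcome_set <- match.arg(outcome_set, c("ventilation", "vent_death", "death"),
                           several.ok = TRUE)
  structure(list(diagnosis = diagnosis, codeset = codeset,
                 age_range = as.integer(age_range),
                 exposure_drug = exposure_drug,
                 mpr_window_days = as.integer(mpr_window_days),
                 mpr_threshold = mpr_threshold,
                 calendar_windows = calendar_windows,
                 outcome_set = outcome_set),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param path Path to a plain-text code list, one code per line; blank lines
#'   and `#` comments are ignored.
#' @export
read_codeset <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Medication possession ratio over a lookback window
#'
#' Sums the days supplied of qualifying fills whose fill date lies in
#' `[index_date - window_days, index_date)` and divides by `window_days`.
#' Supply that would extend past the index date is truncated at the index
#' date. Fills on or after the index date are ignored. Overlapping supplies
#' are summed, not merged, so the MPR can exceed 1.
#'
#' @param fills Data frame with columns `drug_code`, `fill_date`,
#'   `days_supplied` (one patient's fills).
#' @param index_date Index admission date.
#' @param window_days Lookback length in days (> 0).
#' @param drug_filter Exposure drug filter (see [cohort_spec()]).
#' @return The MPR, a nonnegative fraction. Attribute `any_use` records
#'   whether any qualifying fill fell inside the window.
#' @export
#' @examples
#' f <- data.frame(drug_code = "tamsulosin",
#'                 fill_date = as.Date("2010-01-01"), days_supplied = 183)
#' compute_mpr(f, as.Date("2010-12-01"))
compute_mpr <- function(fills, index_date, window_days = 365,
                        drug_filter = "any_alpha_blocker") {
  stopifnot(window_days > 0)
  codes <- drug_filter_codes(drug_filter)
  if (is.null(fills) || nrow(fills) == 0) {
    return(structure(0, any_use = FALSE))
  }
  keep <- fills$drug_code %in% codes &
    fills$fill_date >= index_date - window_days &
    fills$fill_date < index_date
  if (!any(keep)) return(structure(0, any_use = FALSE))
  covered <- pmin(as.numeric(fills$days_supplied[keep]),
                  as.numeric(index_date - fills$fill_date[keep]))
  structure(sum(covered) / window_days, any_use = TRUE)
}

#' Trichotomous exposure classification
#'
#' Exposed iff `mpr >= threshold`; unexposed iff there was no qualifying use
#' at all in the window; excluded (partial user) otherwise. The three classes
#' are exhaustive and mutually exclusive over any fills history.
#'
#' @param mpr Nonnegative MPR value(s).
#' @param any_use Logical: any qualifying fill in the window?
#' @param threshold Exposure threshold, default 0.5.
#' @return Character vector in `{"exposed", "unexposed", "excluded"}`.
#' @export
classify_exposure <- function(mpr, any_use = attr(mpr, "any_use"), threshold = 0.5) {
  stopifnot(all(mpr >= 0))
  if (any(mpr > 0 & !any_use)) {
    stop("inconsistent exposure inputs: mpr > 0 with any_use = FALSE")
  }
  ifelse(mpr >= threshold, "exposed", ifelse(!any_use, "unexposed", "excluded"))
}

year_in_windows <- function(year, windows) {
  Reduce(`|`, lapply(windows, function(w) year >= w[1] & year <= w[2]),
         accumulate = FALSE, init = rep(FALSE, length(year)))
}

split_codes <- function(x) strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)

#' First qualifying (index) admission for one patient
#'
#' @param record A patient record list with an `admissions` data frame, or the
#'   admissions data frame itself (columns `admit_date`, `discharge_date`,
#'   `diagnosis_codes`, ...).
#' @param spec A [cohort_spec()] (its `codeset` is used).
#' @param calendar_windows Admissible index-year windows (list of
#'   `c(start, end)`); required here because the record does not know its
#'   source dialect.
#' @return The earliest admission row (as a one-row data frame) whose
#'   diagnosis codes intersect the codeset and whose admission year falls in
#'   a calendar window, or `NULL` if none qualifies.
#' @export
find_index_admission <- function(record, spec, calendar_windows) {
  adm <- if (is.data.frame(record)) record else record$admissions
  if (is.null(adm) || nrow(adm) == 0) return(NULL)
  has_code <- vapply(split_codes(adm$diagnosis_codes),
                     function(cs) any(cs %in% spec$codeset), logical(1))
  yr <- as.integer(format(adm$admit_date, "%Y"))
  ok <- has_code & year_in_windows(yr, calendar_windows)
  if (!any(ok)) return(NULL)
  cand <- adm[ok, , drop = FALSE]
  cand[order(cand$admit_date)[1], , drop = FALSE]
}

month_number <- function(d) {
  12L * as.integer(format(d, "%Y")) + as.integer(format(d, "%m"))
}

#' Derive outcomes for one patient's index admission
#'
#' Ventilation is 1 iff a ventilation procedure code occurs on the index
#' stay. The composite ventilation-and-death outcome additionally requires
#' death per the source dialect: the in-hospital death flag on the index
#' admission (`in_hospital_flag`), or a recorded death month within one month
#' of the admission month (`death_month_within_1_month`).
#'
#' @param record Patient record list; `record$death_date` (a `Date` or `NA`)
#'   is consulted under the month dialect. A `deaths` data frame with a
#'   `death_date` column is also accepted.
#' @param admission The index admission row (from [find_index_admission()]).
#' @param dialect The [source_dialect()].
#' @return `c(ventilation = 0/1, vent_death = 0/1)`.
#' @export
derive_outcomes <- function(record, admission, dialect) {
  stopifnot(inherits(dialect, "source_dialect"))
  vent <- as.integer(any(split_codes(admission$procedure_codes)[[1]] %in%
                           ventilation_codes()))
  death <- switch(dialect$death_coding,
    in_hospital_flag = isTRUE(admission$died_in_hospital == 1L),
    death_month_within_1_month = {
      dd <- record$death_date
      if (is.null(dd) && !is.null(record$deaths) && nrow(record$deaths)) {
        dd <- min(record$deaths$death_date)
      }
      if (is.null(dd) || length(dd) == 0 || is.na(dd)) FALSE else {
        diff <- month_number(dd) - month_number(admission$admit_date)
        diff >= 0L && diff <= 1L
      }
    },
    stop("configuration error: unknown death coding dialect")
  )
  c(ventilation = vent, vent_death = as.integer(vent == 1L && death))
}

consort_stage <- function(label, n_remaining, n_excluded) {
  data.frame(stage = label, n_remaining = n_remaining, n_excluded = n_excluded,
             stringsAsFactors = FALSE)
}

#' CONSORT-style staged exclusion accounting
#'
#' @param stages Data frame with columns `stage`, `n_remaining`, `n_excluded`.
#' @param source Source label.
#' @return A validated `consort_flow` object. `n_remaining` must be
#'   nonincreasing and each stage's exclusions must reconcile with the
#'   previous stage's count.
#' @export
consort_flow <- function(stages, source = NA_character_) {
  stopifnot(all(c("stage", "n_remaining", "n_excluded") %in% names(stages)))
  obj <- structure(list(stages = stages, source = source), class = "consort_flow")
  validate_consort(obj)
  obj
}

validate_consort <- function(flow) {
  s <- flow$stages
  if (nrow(s) > 1) {
    prev <- s$n_remaining[-nrow(s)]
    cur <- s$n_remaining[-1]
    if (any(cur > prev)) stop("consort validation error: n_remaining increases")
    if (any(prev - cur != s$n_excluded[-1])) {
      stop("consort validation error: exclusions do not reconcile between stages")
    }
  }
  if (any(s$n_excluded < 0)) stop("consort validation error: negative exclusion count")
  invisible(flow)
}

#' @export
print.consort_flow <- function(x, ...) {
  cat("<consort_flow>", if (!is.na(x$source)) x$source else "", "\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

# Distinct-week count of inpatient days inside [lo, index): admissions are
# expanded to calendar-week indices (floor(day/7)) and deduplicated.
weeks_with_admissions <- function(adm, lo_col, index_col) {
  if (nrow(adm) == 0) return(data.table(patient_id = character(), w = integer()))
  a <- adm[, .(patient_id,
               s = pmax(as.numeric(admit_date), as.numeric(get(lo_col))),
               e = pmin(as.numeric(discharge_date), as.numeric(get(index_col)) - 1))]
  a <- a[e >= s]
  if (nrow(a) == 0) return(data.table(patient_id = character(), w = integer()))
  a[, `:=`(ws = floor(s / 7), we = floor(e / 7))]
  nrep <- a$we - a$ws + 1
  long <- data.table(patient_id = rep(a$patient_id, nrep),
                     week_idx = rep(a$ws, nrep) + sequence(nrep) - 1)
  unique(long)[, .(w = .N), by = patient_id]
}

#' Build an analysis-ready cohort from raw claims tables
#'
#' Applies, in order: male sex; a qualifying index admission (diagnosis
#' codeset and calendar windows); age in range at index; 12 months of
#' continuous enrollment before index; and the MPR exposure trichotomy
#' (partial users excluded). Survivors receive derived outcomes and a
#' standardized confounder matrix: age, fiscal year, log(1+x) transforms of
#' four prior-utilization counts (weeks with inpatient admissions and total
#' inpatient days in the prior year, outpatient visits in the prior year,
#' weeks with inpatient admissions in the prior two months), and seven
#' comorbidity flags from any coded encounter in the prior year. Every
#' confounder column is de-meaned and scaled to unit variance cohort-wide.
#'
#' @param records A `claims_source` (from [generate_source()] or
#'   [read_claims_tables()]).
#' @param spec A [cohort_spec()].
#' @param dialect Source dialect; defaults to `records$dialect`.
#' @return A `cohort` data frame (one row per analysis-ready patient) with
#'   columns `patient_id`, `source`, `exposure` (1/0), `age`, `index_date`,
#'   `fiscal_year`, the requested `outcome_*` columns, and standardized
#'   `conf_*` columns. Attributes: `consort` (a [consort_flow()]),
#'   `confounder_names`, `spec`. An empty eligible cohort returns a zero-row
#'   cohort with a warning, never an error.
#' @export
build_cohort <- function(records, spec, dialect = records$dialect) {
  stopifnot(inherits(records, "claims_source"), inherits(spec, "cohort_spec"),
            inherits(dialect, "source_dialect"))
  windows <- if (is.null(spec$calendar_windows)) dialect$icd_era_windows else
    spec$calendar_windows

  pats <- as.data.table(records$patients)
  stages <- consort_stage("all patients", nrow(pats), 0L)
  note <- function(label, dt) {
    stages <<- rbind(stages, consort_stage(
      label, nrow(dt), stages$n_remaining[nrow(stages)] - nrow(dt)))
    dt
  }

  pats <- note("male sex", pats[sex == "male"])

  ## qualifying index admission (earliest codeset hit inside calendar windows)
  adm <- as.data.table(records$admissions)
  if (nrow(adm)) {
    has_code <- vapply(split_codes(adm$diagnosis_codes),
                       function(cs) any(cs %in% spec$codeset), logical(1))
    yr <- as.integer(format(adm$admit_date, "%Y"))
    qual <- adm[has_code & year_in_windows(yr, windows)]
  } else {
    qual <- adm
  }
  if (nrow(qual)) {
    setorder(qual, patient_id, admit_date)
    index <- qual[, head(.SD, 1L), by = patient_id]
    setnames(index, "admit_date", "index_date")
    pats <- note("qualifying index admission",
                 merge(pats, index, by = "patient_id"))
  } else {
    pats <- note("qualifying index admission", pats[0])
  }

  if (nrow(pats)) {
    pats[, age := as.integer(format(index_date, "%Y")) - birth_year]
    pats[, fiscal_year := as.integer(format(index_date, "%Y"))]
  } else {
    pats[, `:=`(age = integer(), fiscal_year = integer(),
                index_date = as.Date(character()))]
  }
  pats <- note(sprintf("age %d-%d at index", spec$age_range[1], spec$age_range[2]),
               pats[age >= spec$age_range[1] & age <= spec$age_range[2]])
  pats <- note("12-month continuous enrollment before index",
               pats[enroll_start <= index_date - 365L & enroll_end >= index_date])

  ## exposure trichotomy
  codes <- drug_filter_codes(spec$exposure_drug)
  fl <- as.data.table(records$fills)[drug_code %in% codes]
  fl <- merge(fl, pats[, .(patient_id, index_date)], by = "patient_id")
  fl <- fl[fill_date >= index_date - spec$mpr_window_days & fill_date < index_date]
  if (nrow(fl)) {
    fl[, covered := pmin(as.numeric(days_supplied), as.numeric(index_date - fill_date))]
    mprs <- fl[, .(mpr = sum(covered) / spec$mpr_window_days), by = patient_id]
  } else {
    mprs <- data.table(patient_id = character(), mpr = numeric())
  }
  pats <- merge(pats, mprs, by = "patient_id", all.x = TRUE)
  pats[, any_use := !is.na(mpr)]
  pats[is.na(mpr), mpr := 0]
  pats[, exposure_class := classify_exposure(mpr, any_use, spec$mpr_threshold)]
  pats <- note("exposure classification (0 < MPR < threshold excluded)",
               pats[exposure_class != "excluded"])
  pats[, exposure := as.integer(exposure_class == "exposed")]

  flow <- consort_flow(stages, source = records$source)
  if (nrow(pats) == 0) {
    warning("empty eligible cohort for source '", records$source, "'")
    out <- data.frame(patient_id = character(), source = character(),
                      exposure = integer(), age = integer(),
                      fiscal_year = integer(), index_date = as.Date(character()))
    attr(out, "consort") <- flow
    attr(out, "confounder_names") <- character()
    attr(out, "spec") <- spec
    class(out) <- c("cohort", "data.frame")
    return(out)
  }

  ## outcomes on the index stay
  vent <- vapply(split_codes(pats$procedure_codes),
                 function(cs) any(cs %in% ventilation_codes()), logical(1))
  deaths <- as.data.table(records$deaths)
  if (nrow(deaths)) {
    first_death <- deaths[, .(death_date = min(death_date)), by = patient_id]
    pats <- merge(pats, first_death, by = "patient_id", all.x = TRUE)
  } else {
    pats[, death_date := as.Date(NA)]
  }
  death_ok <- switch(dialect$death_coding,
    in_hospital_flag = pats$died_in_hospital == 1L,
    death_month_within_1_month = {
      diffm <- month_number(pats$death_date) - month_number(pats$index_date)
      !is.na(diffm) & diffm >= 0L & diffm <= 1L
    })
  pats[, outcome_ventilation := as.integer(vent)]
  pats[, outcome_vent_death := as.integer(vent & death_ok)]
  pats[, outcome_death := as.integer(death_ok)]

  ## confounders -------------------------------------------------------------
  idx <- pats[, .(patient_id, index_date)]
  prior_adm <- merge(as.data.table(records$admissions), idx, by = "patient_id")
  prior_adm <- prior_adm[admit_date < index_date]
  prior_adm[, win_lo := index_date - 365L]
  prior_adm[, win2_lo := index_date - 60L]

  wk_yr <- weeks_with_admissions(prior_adm, "win_lo", "index_date")
  wk_2mo <- weeks_with_admissions(prior_adm[admit_date >= win2_lo |
                                              discharge_date >= win2_lo],
                                  "win2_lo", "index_date")
  days_yr <- if (nrow(prior_adm)) {
    d <- prior_adm[, .(patient_id,
                       s = pmax(as.numeric(admit_date), as.numeric(win_lo)),
                       e = pmin(as.numeric(discharge_date), as.numeric(index_date) - 1))]
    d[e >= s, .(d = sum(e - s + 1)), by = patient_id]
  } else data.table(patient_id = character(), d = numeric())

  vis <- merge(as.data.table(records$visits), idx, by = "patient_id")
  vis <- vis[visit_date >= index_date - 365L & visit_date < index_date]
  nvis <- vis[, .(v = .N), by = patient_id]

  lookup <- function(tab, col) {
    v <- tab[[col]][match(pats$patient_id, tab$patient_id)]
    ifelse(is.na(v), 0, v)
  }
  util <- cbind(
    log_inpatient_weeks = log1p(lookup(wk_yr, "w")),
    log_outpatient_visits = log1p(lookup(nvis, "v")),
    log_inpatient_days = log1p(lookup(days_yr, "d")),
    log_inpatient_weeks_2mo = log1p(lookup(wk_2mo, "w"))
  )

  ## comorbidity flags from any coded encounter in the prior 365 days
  enc <- rbind(
    if (nrow(prior_adm)) prior_adm[admit_date >= win_lo,
                                   .(patient_id, codes = diagnosis_codes)] else NULL,
    if (nrow(vis)) vis[, .(patient_id, codes = diagnosis_codes)] else NULL
  )
  como_sets <- comorbidity_codesets()
  flags <- matrix(0L, nrow(pats), length(como_sets),
                  dimnames = list(NULL, names(como_sets)))
  if (!is.null(enc) && nrow(enc)) {
    spl <- split_codes(enc$codes)
    long <- data.table(patient_id = rep(enc$patient_id, lengths(spl)),
                       code = unlist(spl))
    for (cm in names(como_sets)) {
      hit <- unique(long[code %in% como_sets[[cm]], patient_id])
      flags[, cm] <- as.integer(pats$patient_id %in% hit)
    }
  }

  raw_conf <- cbind(age = as.numeric(pats$age),
                    fiscal_year = as.numeric(pats$fiscal_year), util, flags)
  std_conf <- apply(raw_conf, 2, zscore)
  if (nrow(pats) == 1L) std_conf <- matrix(0, 1, ncol(raw_conf),
                                           dimnames = list(NULL, colnames(raw_conf)))
  colnames(std_conf) <- paste0("conf_", colnames(raw_conf))

  out <- data.frame(
    patient_id = pats$patient_id, source = records$source,
    exposure = pats$exposure, age = pats$age, fiscal_year = pats$fiscal_year,
    index_date = pats$index_date,
    outcome_ventilation = pats$outcome_ventilation,
    outcome_vent_death = pats$outcome_vent_death,
    outcome_death = pats$outcome_death,
    std_conf, stringsAsFactors = FALSE
  )
  attr(out, "consort") <- flow
  attr(out, "confounder_names") <- colnames(std_conf)
  attr(out, "spec") <- spec
  class(out) <- c("cohort", "data.frame")
  out
}

#' Extract the standardized confounder matrix from a cohort
#'
#' @param cohort A `cohort` from [build_cohort()].
#' @param drop Confounder columns to drop (e.g. `"conf_age"` for matching).
#' @return Numeric matrix of standardized confounders.
#' @export
confounder_matrix <- function(cohort, drop = character()) {
  nm <- setdiff(attr(cohort, "confounder_names"), drop)
  as.matrix(cohort[, nm, drop = FALSE])
}
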