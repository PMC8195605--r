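# Hand-built fixtures for the claims schema and cohort container.

test_dialect <- function(death_coding = "in_hospital_flag") {
  source_dialect("test", c(45, 85), death_coding, list(c(2000, 2019)))
}

empty_tables <- function() {
  list(
    patients = data.table::data.table(
      patient_id = character(), sex = character(), birth_year = integer(),
      enroll_start = as.Date(character()), enroll_end = as.Date(character())),
    fills = data.table::data.table(
      patient_id = character(), drug_code = character(),
      fill_date = as.Date(character()), days_supplied = integer()),
    admissions = data.table::data.table(
      patient_id = character(), admit_date = as.Date(character()),
      discharge_date = as.Date(character()), diagnosis_codes = character(),
      procedure_codes = character(), died_in_hospital = integer()),
    visits = data.table::data.table(
      patient_id = character(), visit_date = as.Date(character()),
      diagnosis_codes = character()),
    deaths = data.table::data.table(
      patient_id = character(), death_date = as.Date(character()))
  )
}

manual_source <- function(patients = NULL, fills = NULL, admissions = NULL,
                          visits = NULL, deaths = NULL,
                          dialect = test_dialect()) {
  et <- empty_tables()
  as_dt <- function(x, template) {
    if (is.null(x)) return(template)
    data.table::rbindlist(list(template, x), use.names = TRUE, fill = TRUE)
  }
  structure(list(
    source = dialect$name, dialect = dialect,
    patients = as_dt(patients, et$patients),
    fills = as_dt(fills, et$fills),
    admissions = as_dt(admissions, et$admissions),
    visits = as_dt(visits, et$visits),
    deaths = as_dt(deaths, et$deaths),
    truth = NULL
  ), class = "claims_source")
}

patient_row <- function(id, birth_year = 1950, sex = "male",
                        enroll_start = as.Date("2000-01-01"),
                        enroll_end = as.Date("2019-12-31")) {
  data.frame(patient_id = id, sex = sex, birth_year = birth_year,
             enroll_start = enroll_start, enroll_end = enroll_end)
}

adm_row <- function(id, admit, codes = "518.82", proc = "", died = 0L, los = 5L) {
  admit <- as.Date(admit)
  data.frame(patient_id = id, admit_date = admit,
             discharge_date = admit + los, diagnosis_codes = codes,
             procedure_codes = proc, died_in_hospital = died)
}

fill_row <- function(id, date, days = 30L, drug = "tamsulosin") {
  data.frame(patient_id = id, drug_code = drug, fill_date = as.Date(date),
             days_supplied = days)
}

# A cohort container built directly (bypassing build_cohort) for estimator
# and matching tests. `conf` must be a matrix with conf_-prefixed columns.
toy_cohort <- function(exposure, conf, age = NULL, outcome = NULL,
                       ids = NULL) {
  n <- length(exposure)
  if (is.null(age)) age <- rep(60L, n)
  if (is.null(outcome)) outcome <- rep(0L, n)
  if (is.null(ids)) ids <- sprintf("t%05d", seq_len(n))
  df <- data.frame(patient_id = ids, source = "test",
                   exposure = as.integer(exposure), age = as.integer(age),
                   fiscal_year = 2010L, index_date = as.Date("2010-06-01"),
                   outcome_ventilation = as.integer(outcome),
                   outcome_vent_death = as.integer(outcome),
                   outcome_death = as.integer(outcome),
                   conf, stringsAsFactors = FALSE)
  attr(df, "confounder_names") <- colnames(conf)
  class(df) <- c("cohort", "data.frame")
  df
}

rand_table <- function(max_cell = 30) {
  repeat {
    tb <- contingency_table(sample.int(max_cell, 1), sample.int(max_cell, 1),
                            sample.int(max_cell, 1), sample.int(max_cell, 1))
    if (tb$a + tb$b > 0 && tb$c + tb$d > 0 && tb$a + tb$c > 0 && tb$b + tb$d > 0)
      return(tb)
  }
}

# Rank-based AUROC (Mann-Whitney), independent of any modeling package.
auroc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
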