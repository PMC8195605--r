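#' Drug and diagnosis code sets used by the synthetic schema
#'
#' The synthetic claims tables use a deliberately small, representative code
#' vocabulary: generic drug names for alpha-1 adrenergic receptor (alpha-1-AR)
#' antagonists and a handful of noise drugs, plus one ICD-9 and one ICD-10
#' representative per diagnosis concept. Full AHRQ/CCW dictionaries are out of
#' scope; any code list file with one code per line can be supplied instead.
#'
#' @return `alpha_blocker_codes()`: character vector of alpha-1-AR antagonist
#'   drug codes. `diagnosis_codesets()`: named list of diagnosis code vectors
#'   for the two index conditions. `ventilation_codes()`: procedure codes
#'   flagging mechanical ventilation. `comorbidity_codesets()`: named list of
#'   seven comorbidity code vectors.
#' @export
alpha_blocker_codes <- function() {
  c("tamsulosin", "doxazosin", "alfuzosin", "terazosin", "prazosin", "silodosin")
}

#' @rdname alpha_blocker_codes
#' @export
diagnosis_codesets <- function() {
  list(
    ARD = c("518.82", "R0603"),     # acute respiratory distress, ICD-9 / ICD-10
    pneumonia = c("486", "J189")
  )
}

#' @rdname alpha_blocker_codes
#' @export
ventilation_codes <- function() {
  c("9670", "9671", "9672", "5A1935Z", "5A1945Z", "5A1955Z")
}

#' @rdname alpha_blocker_codes
#' @export
comorbidity_codesets <- function() {
  list(
    hypertension = c("401.9", "I10"),
    ischemic_heart_disease = c("414.01", "I251"),
    acute_mi = c("410.91", "I219"),
    heart_failure = c("428.0", "I509"),
    copd = c("496", "J449"),
    diabetes = c("250.00", "E119"),
    cancer = c("199.1", "C801")
  )
}

noise_drug_codes <- function() {
  c("lisinopril", "metformin", "atorvastatin", "omeprazole", "levothyroxine")
}

# Resolve an exposure-drug filter to a set of drug codes.
drug_filter_codes <- function(drug_filter) {
  if (identical(drug_filter, "any_alpha_blocker")) return(alpha_blocker_codes())
  if (is.character(drug_filter)) return(drug_filter)
  stop("unknown exposure drug filter")
}
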