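#' Derive a child seed from a master seed and a path of stage labels
#'
#' Child seeds are produced by a rolling polynomial hash of the label path so
#' that adding a new pipeline stage never perturbs the seeds of existing
#' stages. All seeds stay below 2^31 - 1.
#'
#' @param master_seed Integer master seed.
#' @param ... Character labels identifying the stage (e.g. `"generate"`,
#'   a source name). Coerced to character and joined with `"/"`.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "generate", "optum")
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  mod <- 2147480009 # largest prime below 2^31 we use for the rolling hash
  h <- as.double(abs(master_seed)) %% mod
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% mod
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Round half away from zero
#'
#' Reporting convention for E-values and summary tables: 2.25 rounds to 2.3,
#' unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stable content hash of a string (hex), used to fingerprint the serialized
# analysis plan. Not cryptographic; collision resistance is irrelevant here.
hash_string <- function(x) {
  mod <- 2147480009
  h1 <- 7; h2 <- 13
  for (code in utf8ToInt(x)) {
    h1 <- (h1 * 31 + code) %% mod
    h2 <- (h2 * 131 + code * 7) %% mod
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

# Wald summary on the log-OR scale shared by several estimators. Protective
# direction means OR < 1, so the one-sided p is P(Z < beta/se).
wald_summary <- function(log_or, var_log_or) {
  se <- sqrt(var_log_or)
  list(
    ci95 = exp(log_or + c(-1, 1) * 1.96 * se),
    p_one_sided = pnorm(log_or / se)
  )
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}
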