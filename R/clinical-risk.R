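#' Define a 10-year clinical risk model
#'
#' A pluggable coefficient specification for a QDiabetes-style proportional
#' hazards risk engine: 10-year risk is
#' \deqn{1 - S_0^{\exp(\eta)}, \quad \eta = \sum_j \beta_j (x_j - c_j)}
#' with log-hazard coefficients `beta`, per-covariate centring constants `c`,
#' and 10-year baseline survival `S0`. Model A uses clinical covariates only;
#' model B additionally requires fasting plasma glucose (`fpg`); model C
#' additionally requires `hba1c`. The published QDiabetes coefficients are
#' not embedded; the engine accepts any coefficient set, and
#' [default_risk_spec()] ships a synthetic calibration.
#'
#' @param name model name, one of "A", "B", "C".
#' @param coefficients named numeric vector of log-hazard weights.
#' @param centers named numeric vector of centring constants (missing names
#'   centre at 0).
#' @param baseline_10yr_survival baseline survival S0 in (0,1).
#' @param sex optionally "male"/"female" to restrict the model to one sex.
#' @return object of class `risk_model_spec`.
#' @export
risk_model_spec <- function(name, coefficients, centers = numeric(0),
                            baseline_10yr_survival, sex = NULL) {
  name <- match.arg(name, c("A", "B", "C"))
  if (baseline_10yr_survival <= 0 || baseline_10yr_survival >= 1) {
    stop("'baseline_10yr_survival' must lie in (0,1)", call. = FALSE)
  }
  required <- names(coefficients)
  if (name == "B" && !"fpg" %in% required) {
    stop("model B requires a fasting glucose ('fpg') coefficient",
         call. = FALSE)
  }
  if (name == "C" && !"hba1c" %in% required) {
    stop("model C requires an 'hba1c' coefficient", call. = FALSE)
  }
  structure(list(name = name, coefficients = coefficients,
                 centers = centers, S0 = baseline_10yr_survival,
                 required = required, sex = sex),
            class = "risk_model_spec")
}

#' @export
print.risk_model_spec <- function(x, ...) {
  cat(sprintf("10-year risk model %s (S0 = %.4f%s)\n", x$name, x$S0,
              if (is.null(x$sex)) "" else paste0(", ", x$sex)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Synthetic default risk model specification
#'
#' A coefficient set on the same covariates as the clinical risk models,
#' calibrated so the synthetic cohort's risk distribution straddles the 10%
#' decision threshold realistically. Shipped for testing and demonstration;
#' it does not reproduce any published calibration.
#'
#' @param name "A", "B", or "C".
#' @return a [risk_model_spec()].
#' @export
default_risk_spec <- function(name = "A") {
  base <- c(age = 0.045, bmi = 0.065, fh_diabetes = 0.35,
            hypertension = 0.15, cvd = 0.10, female = -0.05,
            bangladeshi = 0.05)
  centers <- c(age = 35.4, bmi = 25.8, fpg = 4.9, hba1c = 39.1)
  if (name == "B") base <- c(base, fpg = 0.45)
  if (name == "C") base <- c(base, hba1c = 0.07)
  risk_model_spec(name, base, centers, baseline_10yr_survival = 0.93)
}

#' Apply the longitudinal-analysis inclusion criteria
#'
#' Keeps individuals aged 25 to 84 with no prior type 2 diabetes at the
#' assessment date and no recorded HbA1c above 48 mmol/mol or fasting plasma
#' glucose above 7.0 mmol/L. A missing biomarker is not exclusionary.
#'
#' @param cohort cohort data frame with `age`, `prior_t2d`, and optionally
#'   `hba1c`, `fpg` columns.
#' @param hba1c_max,fpg_max exclusion cutoffs (defaults 48 and 7.0).
#' @return the filtered cohort.
#' @export
apply_inclusion_criteria <- function(cohort, hba1c_max = 48, fpg_max = 7.0) {
  keep <- cohort$age >= 25 & cohort$age <= 84 & cohort$prior_t2d == 0
  if ("hba1c" %in% names(cohort)) {
    keep <- keep & (is.na(cohort$hba1c) | cohort$hba1c <= hba1c_max)
  }
  if ("fpg" %in% names(cohort)) {
    keep <- keep & (is.na(cohort$fpg) | cohort$fpg <= fpg_max)
  }
  cohort[keep, , drop = FALSE]
}

#' Compute 10-year clinical risk
#'
#' Evaluates `1 - S0^exp(eta)` per individual. Rows missing a required
#' covariate receive `NA` with a failure flag rather than an error.
#'
#' @param cohort data frame of covariates.
#' @param spec a [risk_model_spec()].
#' @return list with `risk` (numeric vector in (0,1)) and `failed` (logical
#'   vector marking rows with missing required covariates).
#' @examples
#' spec <- default_risk_spec("A")
#' cc <- data.frame(age = 50, bmi = 30, fh_diabetes = 1, hypertension = 0,
#'                  cvd = 0, female = 1, bangladeshi = 1)
#' risk_10yr(cc, spec)$risk
#' @export
risk_10yr <- function(cohort, spec) {
  stopifnot(inherits(spec, "risk_model_spec"))
  miss_col <- setdiff(spec$required, names(cohort))
  if (length(miss_col) > 0) {
    stop("cohort lacks required covariate(s): ",
         paste(miss_col, collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort)
  eta <- rep(0, n)
  failed <- rep(FALSE, n)
  for (nm in spec$required) {
    x <- cohort[[nm]]
    failed <- failed | is.na(x)
    cen <- if (nm %in% names(spec$centers)) spec$centers[[nm]] else 0
    eta <- eta + spec$coefficients[[nm]] * (x - cen)
  }
  risk <- 1 - spec$S0^exp(eta)
  risk[failed] <- NA_real_
  list(risk = risk, failed = failed)
}

#' Read/write a risk model specification as JSON
#'
#' @param spec a [risk_model_spec()].
#' @param path file path.
#' @return `read_risk_spec` returns a [risk_model_spec()];
#'   `write_risk_spec` returns `path` invisibly.
#' @export
write_risk_spec <- function(spec, path) {
  jsonlite::write_json(
    list(name = spec$name, coefficients = as.list(spec$coefficients),
         centers = as.list(spec$centers), baseline_10yr_survival = spec$S0,
         sex = spec$sex),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_spec
#' @export
read_risk_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("name", "coefficients", "baseline_10yr_survival")) {
    if (is.null(x[[f]])) stop("risk spec JSON missing field '", f, "'",
                              call. = FALSE)
  }
  risk_model_spec(x$name, unlist(x$coefficients),
                  if (length(x$centers)) unlist(x$centers) else numeric(0),
                  x$baseline_10yr_survival, x$sex)
}
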