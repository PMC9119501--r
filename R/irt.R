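#' Fit the integrated risk tool (IRT)
#'
#' Fits, separately in men and women, a logistic regression of 10-year case
#' status on the standardised polygenic score `z`, the clinical risk on the
#' log-odds scale `l = logit(q)`, and their interaction `z * l`. Each sex
#' stratum also gets a centring constant
#' `c = mean(exp(b_prs * z + b_int * z * l))` over its training individuals,
#' so that the PRS-conditional odds multiplier averages one and the combined
#' tool preserves calibration-in-the-large.
#'
#' @param data data frame with columns `q` (clinical 10-year risk in (0,1)),
#'   `prs` (standardised score), `female` (0/1), and `case_10yr` (0/1).
#' @return object of class `irt`: per-sex coefficient sets and centring
#'   constants, with fit diagnostics. A stratum with a single outcome class
#'   is flagged absent rather than fitted.
#' @seealso [predict.irt()], [classify_risk()]
#' @export
fit_irt <- function(data) {
  stopifnot(all(c("q", "prs", "female", "case_10yr") %in% names(data)))
  if (any(data$q <= 0 | data$q >= 1)) {
    stop("clinical risk 'q' must lie strictly within (0,1)", call. = FALSE)
  }
  fit_one <- function(d) {
    if (nrow(d) == 0 || length(unique(d$case_10yr)) < 2) {
      return(list(absent = TRUE, reason = "stratum lacks both outcome classes"))
    }
    l <- qlogis(d$q)
    fit <- suppressWarnings(
      glm(case_10yr ~ prs * l, data = data.frame(case_10yr = d$case_10yr,
                                                 prs = d$prs, l = l),
          family = binomial()))
    cf <- coef(fit)
    mult <- exp(cf[["prs"]] * d$prs + cf[["prs:l"]] * d$prs * l)
    list(absent = FALSE, b0 = cf[["(Intercept)"]], b_prs = cf[["prs"]],
         b_q = cf[["l"]], b_int = cf[["prs:l"]], c = mean(mult),
         converged = fit$converged, vcov = vcov(fit), n = nrow(d))
  }
  out <- list(male = fit_one(data[data$female == 0, , drop = FALSE]),
              female = fit_one(data[data$female == 1, , drop = FALSE]))
  class(out) <- "irt"
  out
}

#' @export
print.irt <- function(x, ...) {
  cat("Integrated risk tool (sex-stratified PRS x clinical-risk model)\n")
  for (s in c("male", "female")) {
    m <- x[[s]]
    if (isTRUE(m$absent)) {
      cat(sprintf("  %s: not fitted (%s)\n", s, m$reason))
    } else {
      cat(sprintf(
        "  %s (n=%d): b_prs=%.3f, b_logit(q)=%.3f, b_int=%.3f, centring c=%.4f\n",
        s, m$n, m$b_prs, m$b_q, m$b_int, m$c))
    }
  }
  invisible(x)
}

#' @export
coef.irt <- function(object, ...) {
  do.call(rbind, lapply(c("male", "female"), function(s) {
    m <- object[[s]]
    if (isTRUE(m$absent)) return(NULL)
    data.frame(sex = s, b0 = m$b0, b_prs = m$b_prs, b_q = m$b_q,
               b_int = m$b_int, c = m$c)
  }))
}

#' @export
summary.irt <- function(object, ...) {
  print(object)
  invisible(coef(object))
}

#' Combine clinical risk and polygenic score into IRT risk
#'
#' For each individual the clinical 10-year risk `q` is converted to odds and
#' multiplied by the centred PRS-conditional odds multiplier
#' `exp(b_prs * z + b_int * z * logit(q)) / c` from the matching sex stratum;
#' the product is mapped back to a probability.
#'
#' @param object a fitted [fit_irt()] model.
#' @param newdata data frame with `q`, `prs`, `female`.
#' @param ... unused.
#' @return numeric vector of IRT 10-year risks.
#' @export
predict.irt <- function(object, newdata, ...) {
  stopifnot(all(c("q", "prs", "female") %in% names(newdata)))
  if (any(newdata$q <= 0 | newdata$q >= 1)) {
    stop("clinical risk 'q' must lie strictly within (0,1)", call. = FALSE)
  }
  out <- rep(NA_real_, nrow(newdata))
  for (s in c("male", "female")) {
    m <- object[[s]]
    idx <- if (s == "male") newdata$female == 0 else newdata$female == 1
    if (!any(idx)) next
    if (isTRUE(m$absent)) {
      stop("no fitted ", s, " stratum available for prediction",
           call. = FALSE)
    }
    q <- newdata$q[idx]
    z <- newdata$prs[idx]
    l <- qlogis(q)
    mult <- exp(m$b_prs * z + m$b_int * z * l) / m$c
    odds <- q / (1 - q) * mult
    out[idx] <- odds / (1 + odds)
  }
  out
}

#' Dichotomise 10-year risk at the clinical decision threshold
#'
#' High risk is strictly greater than the threshold (default 10%); a risk of
#' exactly 10% is classed low.
#'
#' @param risk numeric vector of risks in (0,1).
#' @param threshold decision threshold (default 0.10).
#' @return factor with levels `low`, `high`.
#' @export
classify_risk <- function(risk, threshold = 0.10) {
  stopifnot(all(risk > 0 & risk < 1, na.rm = TRUE))
  factor(ifelse(risk > threshold, "high", "low"), levels = c("low", "high"))
}

#' Serialise a fitted IRT model to JSON
#'
#' @param object a fitted [fit_irt()] model.
#' @param path file path.
#' @return `read_irt` returns the model; `write_irt` returns `path`
#'   invisibly. Variance matrices are not serialised.
#' @export
write_irt <- function(object, path) {
  strip <- function(m) {
    if (isTRUE(m$absent)) return(list(absent = TRUE, reason = m$reason))
    m[c("absent", "b0", "b_prs", "b_q", "b_int", "c", "n")]
  }
  jsonlite::write_json(list(male = strip(object$male),
                            female = strip(object$female)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_irt
#' @export
read_irt <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(x) <- "irt"
  x
}
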