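#' Greedy nearest-neighbour matched controls
#'
#' For each index individual (e.g. a woman with a gestational diabetes
#' history), selects `ratio` controls from the pool by greedy
#' nearest-neighbour matching on the standardised Euclidean distance over the
#' matching variables, without replacement. The order in which index
#' individuals are matched is randomised by the seed, so matching is
#' reproducible.
#'
#' @param index data frame of index individuals with an `id` column.
#' @param pool data frame of candidate controls with an `id` column.
#' @param variables matching variables (default `c("age", "bmi")`); both
#'   frames are standardised jointly.
#' @param ratio controls per index individual (default 1).
#' @param seed RNG seed for the matching order.
#' @return data frame of class `matched_set` with columns `index_id`,
#'   `control_id`, `distance`. When the pool is exhausted a partial matching
#'   is returned with a warning.
#' @export
match_controls <- function(index, pool, variables = c("age", "bmi"),
                           ratio = 1, seed = 1) {
  stopifnot(all(variables %in% names(index)),
            all(variables %in% names(pool)),
            "id" %in% names(index), "id" %in% names(pool))
  all_x <- rbind(index[, variables, drop = FALSE],
                 pool[, variables, drop = FALSE])
  mu <- colMeans(all_x)
  sg <- apply(all_x, 2, sd)
  sg[sg == 0] <- 1
  xi <- sweep(sweep(as.matrix(index[, variables, drop = FALSE]), 2, mu), 2,
              sg, `/`)
  xp <- sweep(sweep(as.matrix(pool[, variables, drop = FALSE]), 2, mu), 2,
              sg, `/`)
  avail <- rep(TRUE, nrow(pool))
  rows <- list()
  with_seed(seed, {
    ord <- sample.int(nrow(index))
    for (i in ord) {
      for (r in seq_len(ratio)) {
        if (!any(avail)) break
        d <- sqrt(colSums((t(xp[avail, , drop = FALSE]) - xi[i, ])^2))
        j <- which(avail)[which.min(d)]
        rows[[length(rows) + 1]] <- data.frame(
          index_id = index$id[i], control_id = pool$id[j],
          distance = min(d), stringsAsFactors = FALSE)
        avail[j] <- FALSE
      }
    }
  })
  out <- do.call(rbind, rows)
  if (nrow(out) < nrow(index) * ratio) {
    warning("control pool exhausted: ", nrow(out), " of ",
            nrow(index) * ratio, " matches made")
  }
  class(out) <- c("matched_set", "data.frame")
  out
}

#' Compare polygenic scores between progressors and non-progressors
#'
#' Welch two-sample comparison of the standardised PRS between two groups
#' (e.g. women with GDM who did versus did not develop type 2 diabetes),
#' optionally with a multivariable logistic contrast adjusting for clinical
#' risk factors.
#'
#' @param prs_a,prs_b PRS vectors for the two groups.
#' @param adjust_data optional data frame with one row per individual across
#'   both groups (group a first) holding adjustment covariates for the
#'   logistic contrast.
#' @return list with group means/SDs, `difference` (a minus b), Welch `t`,
#'   `p`, and, when adjusted, the PRS log-odds coefficient with its p-value.
#' @export
compare_groups <- function(prs_a, prs_b, adjust_data = NULL) {
  stopifnot(length(prs_a) > 0, length(prs_b) > 0)
  if (sd(c(prs_a, prs_b)) == 0) {
    return(list(mean_a = mean(prs_a), mean_b = mean(prs_b),
                sd_a = sd(prs_a), sd_b = sd(prs_b),
                difference = mean(prs_a) - mean(prs_b),
                t = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(prs_a, prs_b)
  out <- list(mean_a = mean(prs_a), mean_b = mean(prs_b),
              sd_a = sd(prs_a), sd_b = sd(prs_b),
              difference = mean(prs_a) - mean(prs_b),
              t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
  if (!is.null(adjust_data)) {
    y <- c(rep(1L, length(prs_a)), rep(0L, length(prs_b)))
    dat <- data.frame(y = y, prs = c(prs_a, prs_b), adjust_data)
    fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial()))
    cf <- summary(fit)$coefficients["prs", ]
    out$adjusted_logor <- cf[["Estimate"]]
    out$adjusted_p <- cf[["Pr(>|z|)"]]
  }
  out
}

#' Hazard ratio per SD of PRS from a Cox model
#'
#' Proportional-hazards fit (Efron ties) of time-to-T2D on the standardised
#' PRS, controlling either for the clinical risk score or for raw clinical
#' risk factors. Non-convergence and degenerate inputs are flagged rather
#' than raised.
#'
#' @param data data frame with `time`, `event`, `prs`, plus adjustment
#'   columns.
#' @param adjustment character vector of adjustment column names (may be
#'   empty).
#' @return list with `hr_per_sd`, `ci` (95%), `p`, and `ok`.
#' @export
prs_hazard <- function(data, adjustment = character(0)) {
  stopifnot(all(c("time", "event", "prs") %in% names(data)))
  if (sum(data$event) == 0 || all(data$time <= 1e-5)) {
    return(list(hr_per_sd = NA_real_, ci = c(NA_real_, NA_real_),
                p = NA_real_, ok = FALSE, reason = "no usable events"))
  }
  rhs <- paste(c("prs", adjustment), collapse = " + ")
  fml <- as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- tryCatch(
    survival::coxph(fml, data = data, ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      withCallingHandlers(
        survival::coxph(fml, data = data, ties = "efron"),
        warning = function(w2) invokeRestart("muffleWarning"))
    })
  if (is.null(fit)) {
    return(list(hr_per_sd = NA_real_, ci = c(NA_real_, NA_real_),
                p = NA_real_, ok = FALSE, reason = "cox fit failed"))
  }
  sm <- summary(fit)
  beta <- coef(fit)[["prs"]]
  se <- sqrt(diag(vcov(fit)))[["prs"]]
  if (!is.finite(beta) || !is.finite(se) || se > 50) {
    return(list(hr_per_sd = NA_real_, ci = c(NA_real_, NA_real_),
                p = NA_real_, ok = FALSE, reason = "non-convergence"))
  }
  list(hr_per_sd = exp(beta), ci = exp(beta + c(-1, 1) * 1.96 * se),
       p = sm$coefficients["prs", "Pr(>|z|)"], ok = TRUE)
}
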