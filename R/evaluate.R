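#' Categorical net reclassification improvement
#'
#' \deqn{NRI = P(up|case) - P(down|case) + P(down|noncase) - P(up|noncase)}
#' where "up" means moving from the low to the high risk class and "down" the
#' reverse. Components are reported separately for cases and non-cases as
#' well as combined.
#'
#' @param old_class,new_class factors or characters with values
#'   `low`/`high` (as from [classify_risk()]).
#' @param outcome binary 0/1 outcome.
#' @return list with `nri`, `nri_case`, `nri_noncase`, the underlying
#'   reclassification counts, and flags for undefined components.
#' @export
categorical_nri <- function(old_class, new_class, outcome) {
  oc <- as.character(old_class)
  nc <- as.character(new_class)
  stopifnot(all(oc %in% c("low", "high")), all(nc %in% c("low", "high")))
  up <- oc == "low" & nc == "high"
  down <- oc == "high" & nc == "low"
  nri_component <- function(sel) {
    n <- sum(sel)
    if (n == 0) return(list(value = NA_real_, undefined = TRUE, n = 0))
    list(value = (sum(up[sel]) - sum(down[sel])) / n, undefined = FALSE,
         n = n)
  }
  case <- nri_component(outcome == 1)
  noncase <- nri_component(outcome == 0)
  nri_case <- case$value
  nri_noncase <- if (noncase$undefined) NA_real_ else -noncase$value
  list(nri = nri_case + nri_noncase, nri_case = nri_case,
       nri_noncase = nri_noncase,
       counts = data.frame(
         status = c("case", "noncase"),
         up = c(sum(up & outcome == 1), sum(up & outcome == 0)),
         down = c(sum(down & outcome == 1), sum(down & outcome == 0)),
         unchanged = c(sum(!up & !down & outcome == 1),
                       sum(!up & !down & outcome == 0))),
       undefined = c(case = case$undefined, noncase = noncase$undefined))
}

#' Continuous net reclassification improvement
#'
#' Same construction as [categorical_nri()] with "up" meaning any increase in
#' estimated risk and "down" any decrease.
#'
#' @param old_risk,new_risk risk vectors in (0,1).
#' @param outcome binary 0/1 outcome.
#' @return as [categorical_nri()].
#' @export
continuous_nri <- function(old_risk, new_risk, outcome) {
  stopifnot(all(old_risk > 0 & old_risk < 1), all(new_risk > 0 & new_risk < 1))
  up <- new_risk > old_risk
  down <- new_risk < old_risk
  nri_component <- function(sel) {
    n <- sum(sel)
    if (n == 0) return(list(value = NA_real_, undefined = TRUE))
    list(value = (sum(up[sel]) - sum(down[sel])) / n, undefined = FALSE)
  }
  case <- nri_component(outcome == 1)
  noncase <- nri_component(outcome == 0)
  nri_noncase <- if (noncase$undefined) NA_real_ else -noncase$value
  list(nri = case$value + nri_noncase, nri_case = case$value,
       nri_noncase = nri_noncase,
       undefined = c(case = case$undefined, noncase = noncase$undefined))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples individuals with replacement `B` times, applies the metric to
#' each resample, and returns the percentile interval. A metric evaluation
#' that errors on a resample causes that resample to be redrawn (count
#' reported).
#'
#' @param metric function taking an integer index vector of resampled rows
#'   and returning a scalar.
#' @param n number of individuals to resample from.
#' @param B number of bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed; identical seeds give identical intervals.
#' @return list with `point` (metric on the original sample), `lo`, `hi`,
#'   `B`, and `n_redrawn`.
#' @export
bootstrap_ci <- function(metric, n, B = 1000, level = 0.95, seed = 1) {
  stopifnot(B >= 2, n >= 1)
  point <- metric(seq_len(n))
  with_seed(seed, {
    vals <- numeric(B)
    redrawn <- 0L
    for (b in seq_len(B)) {
      repeat {
        v <- tryCatch(metric(sample.int(n, n, replace = TRUE)),
                      error = function(e) NULL)
        if (!is.null(v) && is.finite(v)) break
        redrawn <- redrawn + 1L
        if (redrawn > 10L * B) stop("metric failed on too many resamples",
                                    call. = FALSE)
      }
      vals[b] <- v
    }
    a <- (1 - level) / 2
    qs <- quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
    list(point = point, lo = qs[1], hi = qs[2], B = B, n_redrawn = redrawn)
  })
}

#' Harrell's concordance index for a risk score
#'
#' Probability that, of a comparable pair (the earlier time is an observed
#' event), the individual who fails earlier carries the higher predicted
#' risk; ties in risk count one half. Computed via
#' [survival::concordance()] with the risk-score orientation.
#'
#' @param risk predicted risk (higher = worse).
#' @param time follow-up times (> 0).
#' @param event event indicator 0/1.
#' @return list with `c_index` and `n_pairs` (comparable pairs; `c_index` is
#'   NA with a flag when no pair is comparable).
#' @export
c_index <- function(risk, time, event) {
  stopifnot(all(time > 0))
  fit <- survival::concordance(survival::Surv(time, event) ~ risk,
                               reverse = TRUE)
  n_pairs <- sum(fit$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) {
    return(list(c_index = NA_real_, n_pairs = 0, undefined = TRUE))
  }
  list(c_index = as.numeric(fit$concordance), n_pairs = n_pairs,
       undefined = FALSE)
}

#' Metrics within age-by-sex subgroups
#'
#' Evaluates a metric overall and within the four strata formed by an age
#' cutoff (default 40) crossed with sex. Empty strata are flagged.
#'
#' @param cohort data frame with `age` and `female`.
#' @param metric function taking a logical row selector and returning a
#'   scalar (or list with `$nri` etc.; scalars are extracted with
#'   `as.numeric`).
#' @param age_cut age threshold (default 40).
#' @return data frame with one row per stratum (plus overall): stratum
#'   labels, n, and metric value.
#' @export
subgroup_report <- function(cohort, metric, age_cut = 40) {
  strata <- list(
    overall = rep(TRUE, nrow(cohort)),
    young_male = cohort$age < age_cut & cohort$female == 0,
    young_female = cohort$age < age_cut & cohort$female == 1,
    old_male = cohort$age >= age_cut & cohort$female == 0,
    old_female = cohort$age >= age_cut & cohort$female == 1)
  rows <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]]
    val <- if (sum(sel) == 0) NA_real_ else {
      v <- metric(sel)
      if (is.list(v)) v <- v$nri
      as.numeric(v)
    }
    data.frame(stratum = nm, n = sum(sel), value = val,
               empty = sum(sel) == 0)
  })
  do.call(rbind, rows)
}

#' Categorical NRI across a sweep of age cutoffs
#'
#' For each candidate cutoff, computes the categorical NRI (overall and per
#' component) in the younger and older stratum, producing a long-format table
#' ready for plotting.
#'
#' @param cohort data frame with `age`, plus classification inputs.
#' @param old_class,new_class,outcome as in [categorical_nri()].
#' @param cuts numeric vector of at least two age cutoffs.
#' @return data frame with columns cut, stratum, n, nri, nri_case,
#'   nri_noncase, degenerate.
#' @export
age_threshold_sweep <- function(cohort, old_class, new_class, outcome, cuts) {
  stopifnot(length(cuts) >= 2)
  rows <- list()
  for (ct in cuts) {
    for (side in c("young", "old")) {
      sel <- if (side == "young") cohort$age < ct else cohort$age >= ct
      if (sum(sel) == 0 || length(unique(outcome[sel])) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          cut = ct, stratum = side, n = sum(sel), nri = NA_real_,
          nri_case = NA_real_, nri_noncase = NA_real_, degenerate = TRUE)
        next
      }
      r <- categorical_nri(old_class[sel], new_class[sel], outcome[sel])
      rows[[length(rows) + 1]] <- data.frame(
        cut = ct, stratum = side, n = sum(sel), nri = r$nri,
        nri_case = r$nri_case, nri_noncase = r$nri_noncase,
        degenerate = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Descriptive comparison of reclassified individuals
#'
#' Summarises covariate means among individuals reclassified upward,
#' downward, and unchanged by a new tool relative to an old one, and reports
#' Pearson correlations of the PRS with the clinical risk and glycaemic
#' biomarkers. Descriptive plumbing for reporting, not an inferential
#' procedure.
#'
#' @param cohort data frame including the covariates to summarise.
#' @param old_class,new_class risk classes as in [categorical_nri()].
#' @param covariates character vector of cohort columns to summarise.
#' @return list with `table` (means by reclassification direction) and
#'   `prs_correlations` (if `prs`, `q`, `fpg`, `hba1c` columns exist).
#' @export
reclassified_characteristics <- function(cohort, old_class, new_class,
                                         covariates = c("age", "bmi")) {
  dir <- ifelse(old_class == "low" & new_class == "high", "up",
                ifelse(old_class == "high" & new_class == "low", "down",
                       "unchanged"))
  tab <- aggregate(cohort[, covariates, drop = FALSE], list(direction = dir),
                   function(x) mean(x, na.rm = TRUE))
  cors <- NULL
  if ("prs" %in% names(cohort)) {
    targets <- intersect(c("q", "fpg", "hba1c"), names(cohort))
    cors <- vapply(targets, function(v) {
      suppressWarnings(cor(cohort$prs, cohort[[v]],
                           use = "complete.obs"))
    }, numeric(1))
  }
  list(table = tab, prs_correlations = cors)
}
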