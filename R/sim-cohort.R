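#' Generate an individual-level cohort with 10-year incident disease
#'
#' Draws demographics, biomarkers, and comorbidity flags with distributions
#' matching the target population (mean age 35.4 (SD 8.8), 49.8% female, BMI
#' 25.8 (4.6) kg/m2, HbA1c 39.1 (4.3) mmol/mol, fasting glucose 4.9 (0.7)
#' mmol/L, HDL 1.2 (0.3), triglycerides 1.9 (1.3) mmol/L, 35.9% family
#' history, 6.1% hypertension, 2.5% cardiovascular disease), computes the
#' standardised polygenic score from the supplied genotypes and weights, and
#' generates 10-year incident type 2 diabetes from an exponential
#' proportional-hazards model whose log hazard is the clinical linear
#' predictor plus `log(or_per_sd_prs)` times the standardised PRS. The
#' baseline hazard is calibrated so the cohort's expected 10-year cumulative
#' incidence equals `config$target_incidence_10yr`. Censoring is independent
#' exponential plus administrative censoring at 10 years. A GDM history flag
#' is assigned to `gdm_fraction` of women by exponential tilting on the PRS,
#' giving the GDM group a mean PRS elevated by about `gdm_prs_shift` SD.
#'
#' @param config a [sim_config()].
#' @param genotypes output of [generate_genotypes()] (or a compatible list
#'   with `dosages` and `variants`).
#' @param weights a score file (see [score_file()]) whose variants must all be
#'   present in the genotypes.
#' @return an object of class `synthetic_cohort`: list with `cohort` (data
#'   frame), `genotypes` (dosage matrix), and `truth` (all generating
#'   parameters actually used, including the calibrated baseline hazard).
#' @examples
#' cfg <- sim_config(seed = 1, n_individuals = 200, n_loci = 10)
#' g <- generate_genotypes(cfg)
#' w <- score_file(g$variants$id, g$variants$chrom, g$variants$pos,
#'                 g$variants$effect_allele, g$variants$other_allele,
#'                 weight = rnorm(10, 0, 0.05))
#' sc <- generate_cohort(cfg, g, w)
#' mean(sc$cohort$case_10yr)
#' @export
generate_cohort <- function(config, genotypes, weights) {
  stopifnot(inherits(config, "sim_config"))
  dos <- genotypes$dosages
  missing_w <- setdiff(weights$rsID, colnames(dos))
  if (length(missing_w) > 0) {
    stop("score file references variants absent from genotypes: ",
         paste(utils::head(missing_w, 5), collapse = ", "), call. = FALSE)
  }
  n <- nrow(dos)
  raw <- score_individuals(dos, weights)
  z <- if (sd(raw) > 0) (raw - mean(raw)) / sd(raw) else rep(0, n)

  with_seed(config$seed + 3L, {
    female <- rbinom(n, 1, 0.498)
    age <- pmin(pmax(rnorm(n, 35.4, 8.8), 18), 90)
    bmi <- pmax(rnorm(n, 25.8, 4.6), 15)
    hba1c <- pmax(rnorm(n, 39.1, 4.3), 20)
    fpg <- pmax(rnorm(n, 4.9, 0.7), 3)
    hdl <- pmax(rnorm(n, 1.2, 0.3), 0.4)
    tg <- pmax(rnorm(n, 1.9, 1.3), 0.3)
    imd <- pmin(pmax(rnorm(n, 7.4, 2.2), 1), 10)
    bangladeshi <- rbinom(n, 1, 0.699)
    fh_diabetes <- rbinom(n, 1, 0.359)
    hypertension <- rbinom(n, 1, 0.061)
    cvd <- rbinom(n, 1, 0.025)
    prior_t2d <- rep(0L, n)
    pcs <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("pc", 1:10)))

    cb <- config$clinical_betas
    std <- function(x) (x - mean(x)) / sd(x)
    covs <- list(age = std(age), bmi = std(bmi), fh_diabetes = fh_diabetes,
                 hypertension = hypertension, cvd = cvd, female = female,
                 hba1c = std(hba1c), fpg = std(fpg))
    eta_clin <- rep(0, n)
    for (nm in names(cb)) {
      if (!nm %in% names(covs)) {
        stop("unknown covariate in clinical_betas: ", nm, call. = FALSE)
      }
      eta_clin <- eta_clin + cb[[nm]] * covs[[nm]]
    }
    eta <- eta_clin + log(config$or_per_sd_prs) * z

    if (!is.null(config$target_incidence_10yr)) {
      # Calibrate the baseline hazard so the expected observed case fraction
      # (event before both censoring and the 10-year horizon) matches the
      # design incidence: with competing exponential censoring at rate c,
      # P(case) = lam/(lam+c) * (1 - exp(-(lam+c)*10)) per individual.
      target <- config$target_incidence_10yr
      cr <- config$censor_rate
      f <- function(loglam) {
        lam <- exp(loglam) * exp(eta)
        mean(lam / (lam + cr) * (1 - exp(-(lam + cr) * 10))) - target
      }
      lambda0 <- exp(uniroot(f, c(-15, 2), tol = 1e-10)$root)
    } else {
      lambda0 <- -log(config$baseline_10yr_survival) / 10
    }

    t_event <- rexp(n, rate = lambda0 * exp(eta))
    t_cens <- if (config$censor_rate > 0) rexp(n, config$censor_rate)
              else rep(Inf, n)
    time <- pmin(t_event, t_cens, 10)
    event <- as.integer(t_event <= pmin(t_cens, 10))
    time <- pmax(time, 1e-6)

    gdm <- rep(0L, n)
    w_idx <- which(female == 1)
    n_gdm <- round(config$gdm_fraction * length(w_idx))
    if (n_gdm > 0) {
      tilt <- exp(config$gdm_prs_shift * z[w_idx])
      gdm[sample(w_idx, n_gdm, prob = tilt)] <- 1L
    }

    cohort <- data.frame(id = rownames(dos), age = age, female = female,
                         bangladeshi = bangladeshi, bmi = bmi, imd = imd,
                         hba1c = hba1c, fpg = fpg, hdl = hdl, tg = tg,
                         fh_diabetes = fh_diabetes,
                         hypertension = hypertension, cvd = cvd,
                         prior_t2d = prior_t2d, gdm = gdm,
                         prs_raw = raw, prs = z, time = time, event = event,
                         case_10yr = event, stringsAsFactors = FALSE)
    cohort <- cbind(cohort, pcs)
    if (config$missingness > 0) {
      for (col in c("hba1c", "fpg", "hdl", "tg", "bmi")) {
        miss <- runif(n) < config$missingness
        cohort[[col]][miss] <- NA_real_
      }
    }
    truth <- list(seed = config$seed, lambda0 = lambda0,
                  clinical_betas = as.list(config$clinical_betas),
                  log_or_per_sd = log(config$or_per_sd_prs),
                  target_incidence_10yr = config$target_incidence_10yr,
                  censor_rate = config$censor_rate,
                  gdm_fraction = config$gdm_fraction,
                  gdm_prs_shift = config$gdm_prs_shift)
    out <- list(cohort = cohort, genotypes = dos, truth = truth)
    class(out) <- "synthetic_cohort"
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d variants\n",
              nrow(x$cohort), ncol(x$genotypes)))
  cat(sprintf("  10-year cases: %d (%.1f%%), women with GDM history: %d\n",
              sum(x$cohort$case_10yr), 100 * mean(x$cohort$case_10yr),
              sum(x$cohort$gdm)))
  invisible(x)
}

#' Generate a subtype (latent-profile) cohort
#'
#' Draws individuals from a finite mixture of conditionally independent
#' normals over the clinical indicators configured in
#' `config$cluster_params`, records the generating component label, and
#' simulates times to macro- and microvascular complications from
#' cluster-specific exponential hazards with administrative censoring at 10
#' years after diagnosis.
#'
#' @param config a [sim_config()] whose `cluster_params` has k >= 2
#'   components (see [cluster_params_integrated()]).
#' @return data frame with the mixture variables, `prs` (drawn per component
#'   whether or not it is a clustering variable), `true_cluster`, and
#'   `macro_time`/`macro_event`, `micro_time`/`micro_event`.
#' @examples
#' cc <- generate_cluster_cohort(sim_config(seed = 1, n_individuals = 300))
#' table(cc$true_cluster)
#' @export
generate_cluster_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cp <- config$cluster_params
  if (is.null(cp) || nrow(cp) < 2) {
    stop("cluster_params must define at least 2 components", call. = FALSE)
  }
  sds <- as.matrix(cp[, grep("^sd_", names(cp)), drop = FALSE])
  if (any(sds <= 0)) stop("cluster SDs must be strictly positive",
                          call. = FALSE)
  n <- config$n_individuals
  vars <- sub("^mean_", "", grep("^mean_", names(cp), value = TRUE))
  comp_hr <- config$complication_loghr

  with_seed(config$seed + 4L, {
    lab <- sample(cp$label, n, replace = TRUE, prob = cp$prop)
    row <- match(lab, cp$label)
    out <- data.frame(id = sprintf("cl%05d", seq_len(n)),
                      true_cluster = lab, stringsAsFactors = FALSE)
    for (v in vars) {
      mu <- cp[[paste0("mean_", v)]][row]
      sg <- cp[[paste0("sd_", v)]][row]
      x <- rnorm(n, mu, sg)
      if (v %in% c("bmi", "hba1c", "tg", "hdl")) x <- pmax(x, 0.1)
      out[[v]] <- x
    }
    for (type in c("macro", "micro")) {
      loghr <- comp_hr[[type]]
      base <- comp_hr[[paste0(type, "_rate")]]
      hr <- if (is.null(loghr)) rep(0, n) else {
        miss <- setdiff(unique(lab), names(loghr))
        if (length(miss) > 0) {
          loghr <- c(loghr, stats::setNames(rep(0, length(miss)), miss))
        }
        loghr[lab]
      }
      t_ev <- rexp(n, rate = base * exp(hr))
      tm <- pmin(t_ev, 10)
      out[[paste0(type, "_time")]] <- pmax(tm, 1e-6)
      out[[paste0(type, "_event")]] <- as.integer(t_ev <= 10)
    }
    out
  })
}
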