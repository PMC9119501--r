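#' Simulation configuration for the synthetic study
#'
#' Builds the single configuration object consumed by every generator in the
#' synthetic-data module. Defaults reproduce the study conditions the rest of
#' the package assumes: a British-South-Asian-like cohort with a background
#' type 2 diabetes prevalence of 13.6%, a standardised polygenic risk score
#' (PRS) with an odds ratio per standard deviation of 1.57, a 10-year
#' incident-disease design with 18.2% cumulative incidence, a gestational
#' diabetes (GDM) subcohort with an elevated PRS, and a 5-component cluster
#' structure for disease subtyping.
#'
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_individuals number of individuals to simulate.
#' @param n_loci number of variants.
#' @param ld_block_size variants per linkage-disequilibrium (LD) block;
#'   blocks are mutually independent.
#' @param within_block_r2 target squared allelic correlation between variants
#'   in the same block, in `[0, 1)`.
#' @param eaf_range range the effect-allele frequencies are drawn from.
#' @param prevalence_K population prevalence of type 2 diabetes used for
#'   liability-scale conversions.
#' @param or_per_sd_prs generating odds ratio per SD of the standardised PRS.
#' @param clinical_betas named numeric vector of log-hazards for the clinical
#'   covariates entering the incident-disease model. Continuous covariates
#'   are standardised before the linear predictor is formed.
#' @param target_incidence_10yr design 10-year cumulative incidence; the
#'   baseline hazard is calibrated so the simulated cohort attains it. Set to
#'   `NULL` to use `baseline_10yr_survival` directly.
#' @param baseline_10yr_survival 10-year baseline survival used when no
#'   incidence target is given.
#' @param censor_rate independent exponential censoring rate per year.
#' @param gdm_fraction fraction of women carrying a GDM history flag.
#' @param gdm_prs_shift mean PRS elevation (in SD units) of the GDM group.
#' @param n_case_discovery,n_control_discovery discovery GWAS sample sizes
#'   used when simulating summary statistics.
#' @param cluster_params data frame of mixture components for the subtype
#'   generator; see [cluster_params_integrated()].
#' @param complication_loghr named list with numeric vectors `macro` and
#'   `micro` giving per-cluster log hazard ratios for vascular complications.
#' @param missingness per-cell missingness probability for biomarkers
#'   (defaults to 0, complete-case data).
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_individuals = 500, n_loci = 20)
#' cfg$prevalence_K
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 1000L,
                       n_loci = 100L,
                       ld_block_size = 5L,
                       within_block_r2 = 0.3,
                       eaf_range = c(0.05, 0.5),
                       prevalence_K = 0.136,
                       or_per_sd_prs = 1.57,
                       clinical_betas = c(age = 0.40, bmi = 0.30,
                                          fh_diabetes = 0.30,
                                          hypertension = 0.15,
                                          cvd = 0.10, female = -0.05),
                       target_incidence_10yr = 0.182,
                       baseline_10yr_survival = 0.90,
                       censor_rate = 0.02,
                       gdm_fraction = 0.041,
                       gdm_prs_shift = 0.30,
                       n_case_discovery = 80000L,
                       n_control_discovery = 800000L,
                       cluster_params = cluster_params_integrated(),
                       complication_loghr = default_complication_loghr(),
                       missingness = 0) {
  cfg <- list(seed = as.integer(seed),
              n_individuals = as.integer(n_individuals),
              n_loci = as.integer(n_loci),
              ld_block_size = as.integer(ld_block_size),
              within_block_r2 = within_block_r2,
              eaf_range = eaf_range,
              prevalence_K = prevalence_K,
              or_per_sd_prs = or_per_sd_prs,
              clinical_betas = clinical_betas,
              target_incidence_10yr = target_incidence_10yr,
              baseline_10yr_survival = baseline_10yr_survival,
              censor_rate = censor_rate,
              gdm_fraction = gdm_fraction,
              gdm_prs_shift = gdm_prs_shift,
              n_case_discovery = as.integer(n_case_discovery),
              n_control_discovery = as.integer(n_control_discovery),
              cluster_params = cluster_params,
              complication_loghr = complication_loghr,
              missingness = missingness)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_individuals >= 1L, cfg$n_loci >= 1L, cfg$ld_block_size >= 1L)
  if (!is.numeric(cfg$within_block_r2) || cfg$within_block_r2 < 0 ||
      cfg$within_block_r2 >= 1) {
    stop("'within_block_r2' must lie in [0, 1)", call. = FALSE)
  }
  probs <- c(prevalence_K = cfg$prevalence_K,
             gdm_fraction = cfg$gdm_fraction,
             baseline_10yr_survival = cfg$baseline_10yr_survival)
  if (!is.null(cfg$target_incidence_10yr)) {
    probs <- c(probs, target_incidence_10yr = cfg$target_incidence_10yr)
  }
  bad <- probs <= 0 | probs >= 1
  if (any(bad)) {
    stop("probabilities must lie in (0,1): ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (any(cfg$eaf_range <= 0) || any(cfg$eaf_range >= 1) ||
      cfg$eaf_range[1] > cfg$eaf_range[2]) {
    stop("'eaf_range' must be an increasing pair within (0,1)", call. = FALSE)
  }
  stopifnot(cfg$or_per_sd_prs > 0, cfg$censor_rate >= 0,
            cfg$missingness >= 0, cfg$missingness < 1)
  cp <- cfg$cluster_params
  if (!is.null(cp)) {
    if (abs(sum(cp$prop) - 1) > 1e-9) {
      stop("cluster mixing proportions must sum to 1", call. = FALSE)
    }
    sds <- as.matrix(cp[, grep("^sd_", names(cp)), drop = FALSE])
    if (any(sds <= 0)) stop("cluster SDs must be strictly positive",
                            call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  individuals: %d, loci: %d (blocks of %d, target r2 %.2f)\n",
              x$n_individuals, x$n_loci, x$ld_block_size, x$within_block_r2))
  cat(sprintf("  prevalence K = %.3f, OR per SD of PRS = %.2f\n",
              x$prevalence_K, x$or_per_sd_prs))
  if (!is.null(x$target_incidence_10yr)) {
    cat(sprintf("  10-year incidence target = %.3f\n", x$target_incidence_10yr))
  }
  if (!is.null(x$cluster_params)) {
    cat(sprintf("  subtype mixture: %d components (%s)\n",
                nrow(x$cluster_params),
                paste(x$cluster_params$label, collapse = ", ")))
  }
  invisible(x)
}

#' Default five-component subtype mixtures
#'
#' Component labels, mixing proportions, and per-variable means/SDs for the
#' latent-profile subtype generator. The "integrated" parameterisation uses
#' age, BMI, HbA1c, serum triglycerides, and the T2D PRS as indicators; the
#' "clinical" parameterisation uses age, BMI, HbA1c, triglycerides, and HDL
#' with PRS as a non-clustering companion variable. Mixing proportions follow
#' the observed subgroup sizes (556:1180:37:579:3489 for the integrated model,
#' 211:861:32:95:3067 for the clinical model).
#'
#' @return a data frame with columns `label`, `prop`, and `mean_*`/`sd_*`
#'   pairs per variable.
#' @export
cluster_params_integrated <- function() {
  data.frame(
    label = c("MOD", "MARD", "SIRD", "IRD", "pSIDD"),
    prop  = c(556, 1180, 37, 579, 3489) / 5841,
    mean_age = c(44.8, 61.6, 43.7, 42.8, 41.6),
    sd_age   = c(9.6, 7.6, 11.3, 9.9, 7.6),
    mean_bmi = c(37.2, 27.5, 28.1, 27.8, 26.7),
    sd_bmi   = c(3.9, 3.4, 3.7, 3.8, 3.3),
    mean_hba1c = c(60.0, 53.1, 72.8, 63.3, 60.0),
    sd_hba1c   = c(17.1, 11.6, 26.8, 19.1, 16.5),
    mean_tg = c(1.77, 1.62, 13.0, 4.97, 1.66),
    sd_tg   = c(0.73, 0.70, 3.63, 1.05, 0.74),
    mean_prs = c(0.16, -0.10, 0.41, 0.25, 0.48),
    sd_prs   = c(0.91, 0.92, 0.96, 1.02, 0.95),
    stringsAsFactors = FALSE
  )
}

#' @rdname cluster_params_integrated
#' @export
cluster_params_clinical <- function() {
  data.frame(
    label = c("MOD", "MARD", "SIRD", "MD", "CUD"),
    prop  = c(211, 861, 32, 95, 3067) / 4266,
    mean_age = c(44.5, 50.9, 43.1, 49.3, 45.2),
    sd_age   = c(11.4, 12.2, 10.9, 12.3, 10.6),
    mean_bmi = c(40.2, 27.6, 28.2, 27.1, 27.5),
    sd_bmi   = c(3.6, 4.0, 3.9, 5.2, 3.7),
    mean_hba1c = c(57.5, 53.4, 71.9, 55.9, 59.0),
    sd_hba1c   = c(15.8, 13.4, 26.9, 17.63, 16.4),
    mean_tg = c(1.72, 1.39, 12.2, 1.21, 1.97),
    sd_tg   = c(0.73, 0.63, 3.95, 0.43, 1.08),
    mean_hdl = c(1.17, 1.45, 0.79, 2.07, 0.99),
    sd_hdl   = c(0.24, 0.15, 0.21, 0.20, 0.17),
    mean_prs = c(0.07, 0.23, 0.29, 0.26, 0.34),
    sd_prs   = c(1.02, 0.97, 1.14, 1.09, 0.97),
    stringsAsFactors = FALSE
  )
}

#' Default per-cluster complication log hazard ratios
#'
#' Macrovascular rates are elevated in MARD and MOD, microvascular rates in
#' IRD and MARD, relative to the remaining clusters, mirroring the pattern of
#' differential progression the subtype analysis is designed to detect.
#'
#' @return list with named numeric vectors `macro` and `micro` and baseline
#'   yearly rates `macro_rate`, `micro_rate`.
#' @export
default_complication_loghr <- function() {
  list(macro = c(MOD = 0.40, MARD = 0.50, SIRD = 0, IRD = 0, pSIDD = 0),
       micro = c(MOD = 0, MARD = 0.40, SIRD = 0, IRD = 0.60, pSIDD = 0),
       macro_rate = 0.018, micro_rate = 0.037)
}
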