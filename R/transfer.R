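#' Single-variant logistic association test
#'
#' Per-allele log odds ratio for a binary phenotype from maximum-likelihood
#' logistic regression of the phenotype on the dosage plus covariates, with a
#' two-sided Wald p-value. Degenerate inputs (constant dosage, fewer than two
#' individuals in either phenotype class, or separation) are returned as
#' flagged failure records rather than errors, so panel-wide scans can
#' proceed.
#'
#' @param dosage numeric dosage vector.
#' @param phenotype binary 0/1 vector.
#' @param covariates optional numeric matrix of adjustment covariates.
#' @return list with `beta`, `se`, `p`, and `ok` (FALSE with a `reason` when
#'   the test could not be run).
#' @examples
#' set.seed(1)
#' d <- rbinom(500, 2, 0.3)
#' y <- rbinom(500, 1, plogis(-1 + 0.4 * d))
#' assoc_test(d, y)$beta
#' @export
assoc_test <- function(dosage, phenotype, covariates = NULL) {
  fail <- function(reason) list(beta = NA_real_, se = NA_real_, p = NA_real_,
                                ok = FALSE, reason = reason)
  if (length(unique(phenotype)) < 2 || min(table(phenotype)) < 2) {
    return(fail("fewer than 2 of each phenotype class"))
  }
  if (var(dosage) == 0) return(fail("zero-variance dosage"))
  X <- if (is.null(covariates)) data.frame(dosage = dosage)
       else data.frame(dosage = dosage, covariates)
  fit <- tryCatch(
    suppressWarnings(glm(phenotype ~ ., data = X, family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(fail("non-convergence"))
  cf <- summary(fit)$coefficients
  if (!"dosage" %in% rownames(cf)) return(fail("dosage dropped from fit"))
  se <- cf["dosage", "Std. Error"]
  if (!is.finite(se) || se > 100) return(fail("separation"))
  list(beta = cf["dosage", "Estimate"], se = se,
       p = cf["dosage", "Pr(>|z|)"], ok = TRUE, reason = NA_character_)
}

#' Analytic replication power for a discovery locus
#'
#' Power of the two-sided Wald test at level `alpha` in the target sample,
#' assuming the discovery effect size and using the additive-logistic
#' standard-error approximation
#' \deqn{se \approx 1/\sqrt{2 f (1-f) N \phi(1-\phi)}}
#' with `f` the target effect-allele frequency, `N = n_case + n_control`, and
#' `phi` the case fraction. Power is `P(|Z| > z_{alpha/2})` for
#' `Z ~ Normal(beta/se, 1)`; at `beta = 0` it equals `alpha` exactly.
#'
#' @param beta_discovery discovery log odds ratio per allele.
#' @param eaf_target effect-allele frequency in the target population.
#' @param n_case,n_control target sample sizes.
#' @param alpha two-sided significance level (default 0.05).
#' @return replication power, a probability. Vectorised over loci.
#' @examples
#' replication_power(0.1, 0.3, 4000, 18000)
#' @export
replication_power <- function(beta_discovery, eaf_target, n_case, n_control,
                              alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0,1)",
                                     call. = FALSE)
  if (any(eaf_target <= 0) || any(eaf_target >= 1)) {
    stop("'eaf_target' must lie strictly within (0,1)", call. = FALSE)
  }
  N <- n_case + n_control
  phi <- n_case / N
  se <- 1 / sqrt(2 * eaf_target * (1 - eaf_target) * N * phi * (1 - phi))
  zc <- qnorm(1 - alpha / 2)
  mu <- beta_discovery / se
  pnorm(-zc - mu) + pnorm(mu - zc)
}

#' Expected number of replicating loci
#'
#' Sums per-locus replication power to the expected replication count, with
#' the corresponding expected proportion.
#'
#' @param power numeric vector of per-locus replication powers.
#' @return list with `expected_count` and `expected_proportion`.
#' @export
expected_replications <- function(power) {
  stopifnot(is.numeric(power), length(power) >= 1, !anyNA(power))
  list(expected_count = sum(power),
       expected_proportion = sum(power) / length(power))
}

#' One-sided binomial test of observed vs expected replication
#'
#' Exact lower-tail probability `P(X <= observed)` for
#' `X ~ Binomial(n, expected_proportion)`: the evidence that fewer loci
#' replicate than the power calculation predicts.
#'
#' @param observed observed replication count.
#' @param expected_proportion expected per-locus replication probability.
#' @param n number of loci assessed.
#' @return the one-sided p-value.
#' @examples
#' transfer_test(76, 0.30, 338)  # 0.001 to 3 decimal places
#' @export
transfer_test <- function(observed, expected_proportion, n) {
  if (expected_proportion <= 0 || expected_proportion >= 1) {
    stop("'expected_proportion' must lie strictly within (0,1)", call. = FALSE)
  }
  stopifnot(observed >= 0, observed <= n)
  pbinom(observed, size = n, prob = expected_proportion)
}

#' Classify loci as transferable
#'
#' A locus is transferable when its target-sample association is significant
#' at `alpha` and (by default) directionally consistent with the discovery
#' effect. Also reports the stricter Bonferroni count at `alpha / n`.
#'
#' @param loci data frame with at least `p_target`, `beta_target`, and
#'   `beta_discovery` columns.
#' @param alpha significance level (default 0.05).
#' @param require_direction require sign agreement between discovery and
#'   target effects (default TRUE).
#' @param one_sided use a one-sided target p-value (halve a two-sided p when
#'   the direction agrees) instead of the two-sided criterion.
#' @return list with the input `loci` gaining a logical `transferable`
#'   column, `n_transferable`, `pct_transferable`, and `n_bonferroni`.
#' @export
classify_transferable <- function(loci, alpha = 0.05,
                                  require_direction = TRUE,
                                  one_sided = FALSE) {
  stopifnot(all(c("p_target", "beta_target", "beta_discovery") %in%
                  names(loci)))
  same_dir <- sign(loci$beta_target) == sign(loci$beta_discovery)
  p_use <- if (one_sided) ifelse(same_dir, loci$p_target / 2, 1)
           else loci$p_target
  ok <- p_use < alpha
  if (require_direction) ok <- ok & same_dir
  loci$transferable <- ok
  n <- nrow(loci)
  p_bonf <- if (one_sided) ifelse(same_dir, loci$p_target / 2, 1)
            else loci$p_target
  bonf <- sum(p_bonf < alpha / n & (!require_direction | same_dir))
  list(loci = loci, n_transferable = sum(ok),
       pct_transferable = 100 * sum(ok) / n, n_bonferroni = bonf)
}
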