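#' Construct a polygenic score file
#'
#' A score file is a data frame in the PGS-Catalog dialect: one row per
#' variant with its effect allele and per-allele log-odds weight.
#'
#' @param rsID variant identifiers (must be unique).
#' @param chr_name,chr_position chromosome and 1-based position.
#' @param effect_allele,other_allele allele strings (upper-cased).
#' @param weight per-allele effect weight on the log-odds scale.
#' @param threshold,source optional metadata stored as attributes.
#' @return data frame of class `score_file`.
#' @export
score_file <- function(rsID, chr_name, chr_position, effect_allele,
                       other_allele, weight, threshold = NA_real_,
                       source = "unspecified") {
  if (anyDuplicated(rsID)) stop("duplicate variant ids in score file",
                                call. = FALSE)
  if (any(!is.finite(weight))) stop("score weights must be finite",
                                    call. = FALSE)
  out <- data.frame(rsID = as.character(rsID), chr_name = as.character(chr_name),
                    chr_position = as.integer(chr_position),
                    effect_allele = toupper(effect_allele),
                    other_allele = toupper(other_allele),
                    effect_weight = weight, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "source") <- source
  class(out) <- c("score_file", "data.frame")
  out
}

#' Greedy LD clumping of summary statistics
#'
#' Standard clumping-and-thresholding index-variant selection: variants are
#' visited in order of ascending p-value (ties broken by chromosome then
#' position); each index variant removes all not-yet-selected variants within
#' `window_kb` whose squared allelic correlation with it, estimated from the
#' reference dosage panel, exceeds `r2_threshold`.
#'
#' @param summary summary-statistic data frame (columns CHR, POS, SNP, P).
#' @param reference dosage matrix with variant ids as column names, used to
#'   estimate LD; summary variants missing from it are dropped with a
#'   warning.
#' @param r2_threshold squared-correlation threshold (default 0.1).
#' @param window_kb clumping window in kilobases (default 250).
#' @param p_cutoff only variants with P below this enter clumping
#'   (default 1, i.e. all).
#' @return character vector of index variant ids (empty when no variant
#'   passes the cutoff).
#' @export
ld_clump <- function(summary, reference, r2_threshold = 0.1,
                     window_kb = 250, p_cutoff = 1) {
  stopifnot(all(c("CHR", "POS", "SNP", "P") %in% names(summary)))
  if (nrow(summary) == 0) return(character(0))
  keep <- summary$SNP %in% colnames(reference)
  if (any(!keep)) {
    warning(sum(!keep), " summary variants absent from the reference panel",
            " were dropped")
    summary <- summary[keep, , drop = FALSE]
  }
  summary <- summary[summary$P < p_cutoff, , drop = FALSE]
  if (nrow(summary) == 0) return(character(0))
  ord <- order(summary$P, summary$CHR, summary$POS)
  summary <- summary[ord, , drop = FALSE]
  active <- rep(TRUE, nrow(summary))
  index <- character(0)
  win <- window_kb * 1000
  while (any(active)) {
    i <- which(active)[1]
    index <- c(index, summary$SNP[i])
    active[i] <- FALSE
    near <- which(active & summary$CHR == summary$CHR[i] &
                    abs(summary$POS - summary$POS[i]) <= win)
    if (length(near) > 0) {
      r <- suppressWarnings(
        cor(reference[, summary$SNP[i]], reference[, summary$SNP[near],
                                                   drop = FALSE]))
      r2 <- as.numeric(r)^2
      r2[is.na(r2)] <- 0
      active[near[r2 > r2_threshold]] <- FALSE
    }
  }
  index
}

#' Build clumping-and-thresholding scores over a p-value grid
#'
#' One score file per threshold, containing the index variants whose
#' discovery p-value falls below it, weighted by the discovery beta. Scores
#' are nested by construction: the score at a smaller threshold is a subset
#' of the score at a larger one.
#'
#' @param summary summary statistics (CHR, POS, SNP, EA, OA, BETA, P).
#' @param index character vector of index variant ids from [ld_clump()].
#' @param thresholds ascending vector of p-value thresholds.
#' @return named list of [score_file()] objects, one per threshold.
#' @export
build_ct_scores <- function(summary, index, thresholds) {
  stopifnot(!is.unsorted(thresholds))
  idx <- summary[summary$SNP %in% index, , drop = FALSE]
  out <- lapply(thresholds, function(t) {
    sel <- idx[idx$P < t, , drop = FALSE]
    score_file(sel$SNP, sel$CHR, sel$POS, sel$EA, sel$OA, sel$BETA,
               threshold = t, source = "C+T")
  })
  names(out) <- format(thresholds, scientific = TRUE, digits = 3)
  out
}

#' Harmonise a score file to a genotype panel's allele orientation
#'
#' Matches score-file entries to panel variants by id. Entries whose alleles
#' are swapped relative to the panel get their weight sign flipped;
#' strand-ambiguous (A/T, C/G) entries are dropped when `drop_ambiguous`;
#' entries with irreconcilable alleles are dropped. Counts are reported via
#' attributes.
#'
#' @param score a [score_file()].
#' @param variants panel metadata with `id`, `effect_allele`, `other_allele`.
#' @param drop_ambiguous drop strand-ambiguous variants (default TRUE).
#' @return harmonised score file with attributes `n_flipped`, `n_dropped`.
#' @export
harmonise_score <- function(score, variants, drop_ambiguous = TRUE) {
  m <- match(score$rsID, variants$id)
  present <- !is.na(m)
  sc <- score[present, , drop = FALSE]
  pv <- variants[m[present], , drop = FALSE]
  ambiguous <- (sc$effect_allele == "A" & sc$other_allele == "T") |
    (sc$effect_allele == "T" & sc$other_allele == "A") |
    (sc$effect_allele == "C" & sc$other_allele == "G") |
    (sc$effect_allele == "G" & sc$other_allele == "C")
  same <- sc$effect_allele == pv$effect_allele &
    sc$other_allele == pv$other_allele
  swap <- sc$effect_allele == pv$other_allele &
    sc$other_allele == pv$effect_allele
  keep <- (same | swap) & !(drop_ambiguous & ambiguous)
  out <- sc[keep, , drop = FALSE]
  flip <- swap[keep]
  out$effect_weight[flip] <- -out$effect_weight[flip]
  ea <- out$effect_allele
  out$effect_allele[flip] <- out$other_allele[flip]
  out$other_allele[flip] <- ea[flip]
  n_drop <- nrow(score) - nrow(out)
  if (n_drop > 0) {
    message(n_drop, " score variants dropped during harmonisation (absent, ",
            "allele-mismatched, or strand-ambiguous)")
  }
  attr(out, "n_flipped") <- sum(flip)
  attr(out, "n_dropped") <- n_drop
  class(out) <- c("score_file", "data.frame")
  out
}

#' Compute raw polygenic scores
#'
#' `raw_i = sum_v weight_v * dosage_iv` over the score variants present in
#' the panel; absent variants are excluded (count reported via the
#' `n_excluded` attribute) and missing dosages are mean-imputed as twice the
#' panel allele frequency.
#'
#' @param dosages individuals x variants dosage matrix with variant ids as
#'   column names.
#' @param score a [score_file()] already harmonised to the panel orientation.
#' @return numeric vector of raw scores, one per individual.
#' @examples
#' d <- matrix(0:2, 3, 1, dimnames = list(NULL, "v1"))
#' s <- score_file("v1", "1", 1, "A", "G", 0.2)
#' score_individuals(d, s)  # 0 0.2 0.4
#' @export
score_individuals <- function(dosages, score) {
  present <- score$rsID %in% colnames(dosages)
  sc <- score[present, , drop = FALSE]
  if (nrow(sc) == 0) {
    out <- rep(0, nrow(dosages))
    attr(out, "n_excluded") <- nrow(score)
    return(out)
  }
  G <- dosages[, sc$rsID, drop = FALSE]
  if (anyNA(G)) {
    means <- colMeans(G, na.rm = TRUE)
    for (j in seq_len(ncol(G))) {
      miss <- is.na(G[, j])
      if (any(miss)) G[miss, j] <- means[j]
    }
  }
  out <- as.numeric(G %*% sc$effect_weight)
  attr(out, "n_excluded") <- sum(!present)
  out
}

#' Standardise a polygenic score by principal-component residualisation
#'
#' Regresses the raw score on the supplied principal components (plus an
#' intercept) by least squares and scales the residual to unit standard
#' deviation, giving a score with mean 0 and SD 1 that is orthogonal to the
#' PCs. Collinear PC columns are dropped with a warning.
#'
#' @param raw raw score vector.
#' @param pcs numeric matrix of principal components (typically n x 10).
#' @return standardised score vector (mean 0, SD 1).
#' @export
standardize_prs <- function(raw, pcs) {
  X <- cbind(1, as.matrix(pcs))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("rank-deficient PC matrix; dropping ",
            ncol(X) - qr_x$rank, " collinear column(s)")
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  }
  res <- qr.resid(qr(X), raw)
  s <- sd(res)
  if (s < .Machine$double.eps^0.5) {
    stop("raw score is numerically linear in the PCs; residual SD is zero",
         call. = FALSE)
  }
  (res - mean(res)) / s
}

# Rank-statistic AUC (Mann-Whitney), ties counted one half.
auc_rank <- function(score, outcome) {
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Nagelkerke pseudo R2 of a fitted binomial glm (unweighted observations).
nagelkerke_r2 <- function(fit) {
  y <- fit$y
  n <- length(y)
  ll_full <- as.numeric(logLik(fit))
  p0 <- mean(y)
  ll_null <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  cox_snell <- 1 - exp(2 * (ll_null - ll_full) / n)
  cox_snell / (1 - exp(2 * ll_null / n))
}

#' Convert an observed-scale Nagelkerke R2 to the liability scale
#'
#' Case-control ascertainment-adjusted conversion (Lee et al.): with
#' population prevalence `K`, sample case proportion `P`, threshold
#' `t = qnorm(1-K)`, density `z = dnorm(t)`, and mean liability of cases
#' `i = z/K`,
#' \deqn{R^2_l = C R^2_N / (1 + C \theta R^2_N)}
#' where `C = K(1-K) K(1-K) / (z^2 P(1-P))` and
#' `theta = i ((P-K)/(1-K)) (i ((P-K)/(1-K)) - t)`.
#'
#' @param r2_nagelkerke observed-scale Nagelkerke pseudo R2.
#' @param K population prevalence.
#' @param P sample case proportion.
#' @return liability-scale R2 (0 when the observed R2 is 0).
#' @export
liability_r2 <- function(r2_nagelkerke, K, P) {
  stopifnot(K > 0, K < 1, P > 0, P < 1)
  t <- qnorm(1 - K)
  z <- dnorm(t)
  i <- z / K
  cc <- K * (1 - K) * K * (1 - K) / (z^2 * P * (1 - P))
  theta <- i * ((P - K) / (1 - K)) * (i * ((P - K) / (1 - K)) - t)
  cc * r2_nagelkerke / (1 + cc * theta * r2_nagelkerke)
}

#' Evaluate a standardised polygenic score
#'
#' Fits the full logistic model (outcome ~ PRS + covariates) and the
#' reference model (covariates only), and reports: rank-statistic AUC of
#' both, the incremental AUC, the incremental Nagelkerke R2 converted to the
#' liability scale with population prevalence `K`, and the odds ratio per SD
#' of PRS from the full model with its Wald 95% CI. Optional bootstrap CIs
#' for AUC-based quantities.
#'
#' @param standardized standardised PRS vector.
#' @param outcome binary 0/1 outcome.
#' @param covariates data frame or matrix of reference-model covariates
#'   (e.g. age, sex, 10 PCs); may be NULL for an intercept-only reference.
#' @param K population prevalence for the liability conversion
#'   (default 0.136).
#' @param boot number of bootstrap replicates for CIs (0 = none).
#' @param seed seed for the bootstrap.
#' @return list with `auc_full`, `auc_ref`, `incremental_auc`,
#'   `r2_liability`, `or_per_sd` (with `or_ci`), and optional bootstrap CIs.
#' @export
evaluate_prs <- function(standardized, outcome, covariates = NULL,
                         K = 0.136, boot = 0, seed = 1) {
  if (length(unique(outcome)) < 2) {
    stop("outcome has a single class; evaluation undefined", call. = FALSE)
  }
  dat <- data.frame(y = outcome, prs = standardized)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  full <- glm(y ~ ., data = dat, family = binomial())
  ref <- if (is.null(covariates)) glm(y ~ 1, data = dat, family = binomial())
         else glm(y ~ . - prs, data = dat, family = binomial())
  auc_full <- auc_rank(predict(full), outcome)
  auc_ref <- if (is.null(covariates)) 0.5 else auc_rank(predict(ref), outcome)
  r2_inc <- nagelkerke_r2(full) - nagelkerke_r2(ref)
  P <- mean(outcome)
  cf <- summary(full)$coefficients["prs", ]
  out <- list(auc_full = auc_full, auc_ref = auc_ref,
              incremental_auc = auc_full - auc_ref,
              r2_liability = liability_r2(max(r2_inc, 0), K, P),
              or_per_sd = exp(cf["Estimate"]),
              or_ci = exp(cf["Estimate"] + c(-1, 1) * 1.96 * cf["Std. Error"]))
  if (boot > 0) {
    n <- length(outcome)
    stat <- function(idx) {
      d <- dat[idx, , drop = FALSE]
      f <- suppressWarnings(glm(y ~ ., data = d, family = binomial()))
      r <- if (is.null(covariates))
        glm(y ~ 1, data = d, family = binomial())
      else suppressWarnings(glm(y ~ . - prs, data = d, family = binomial()))
      a_r <- if (is.null(covariates)) 0.5 else auc_rank(predict(r), d$y)
      auc_rank(predict(f), d$y) - a_r
    }
    bs <- with_seed(seed, {
      replicate(boot, stat(sample.int(n, n, replace = TRUE)))
    })
    out$incremental_auc_ci <- unname(quantile(bs, c(0.025, 0.975)))
  }
  out
}

#' Combine two standardised scores by validation-set mixing
#'
#' Forms `alpha * prs_a + (1 - alpha) * prs_b` and picks `alpha` on a grid to
#' maximise AUC against the validation outcome. When several grid points tie
#' (within 1e-12), the midpoint of the tied range is returned with a note.
#'
#' @param prs_a,prs_b standardised scores on the same individuals.
#' @param outcome validation binary outcome.
#' @param grid mixing grid (default `seq(0, 1, 0.1)`).
#' @return list with `alpha`, `mixed` (the combined score), `auc`, and
#'   `note`.
#' @export
combine_prs <- function(prs_a, prs_b, outcome, grid = seq(0, 1, by = 0.1)) {
  aucs <- vapply(grid, function(a) {
    auc_rank(a * prs_a + (1 - a) * prs_b, outcome)
  }, numeric(1))
  best <- aucs >= max(aucs) - 1e-12
  note <- NA_character_
  if (sum(best) > 1) {
    alpha <- grid[best][ceiling(sum(best) / 2)]
    note <- "multiple grid points tied on AUC; midpoint of tied range used"
  } else {
    alpha <- grid[which.max(aucs)]
  }
  list(alpha = alpha, mixed = alpha * prs_a + (1 - alpha) * prs_b,
       auc = max(aucs), grid = grid, grid_auc = aucs, note = note)
}
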