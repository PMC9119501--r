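#' One-way ANOVA of the polygenic score across subtype clusters
#'
#' Fixed-effects one-way analysis of variance of a standardised PRS across
#' hard cluster labels.
#'
#' @param labels cluster labels (coerced to factor).
#' @param prs numeric score vector.
#' @return list with `F`, `p`, `df`, and a `degenerate` flag when fewer than
#'   two clusters have at least two members.
#' @export
prs_anova <- function(labels, prs) {
  labels <- factor(labels)
  sizes <- table(labels)
  if (sum(sizes >= 2) < 2) {
    return(list(F = NA_real_, p = NA_real_, df = c(NA, NA),
                degenerate = TRUE))
  }
  fit <- aov(prs ~ labels)
  tab <- summary(fit)[[1]]
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = tab$Df, degenerate = FALSE)
}

#' Trait-PRS contrasts between clusters and nondiabetic controls
#'
#' One-tailed Welch t tests of each glycaemic trait PRS between every
#' cluster's members and a control group, Bonferroni-adjusted over the whole
#' (cluster x trait) family. The tail is configured per trait (`"greater"`
#' tests for elevation in the cluster).
#'
#' @param members data frame with a `cluster` column plus one column per
#'   trait PRS.
#' @param controls data frame with the same trait columns.
#' @param traits character vector of trait column names.
#' @param directions named character vector ("greater"/"less") per trait;
#'   default all "greater".
#' @return data frame: cluster, trait, mean_difference, p, p_bonferroni, and
#'   the Bonferroni factor used (the number of tests).
#' @export
trait_prs_contrast <- function(members, controls, traits,
                               directions = NULL) {
  stopifnot(nrow(controls) > 0, "cluster" %in% names(members),
            all(traits %in% names(members)),
            all(traits %in% names(controls)))
  if (is.null(directions)) {
    directions <- setNames(rep("greater", length(traits)), traits)
  }
  clusters <- unique(members$cluster)
  rows <- list()
  for (cl in clusters) {
    x <- members[members$cluster == cl, , drop = FALSE]
    for (tr in traits) {
      tt <- t.test(x[[tr]], controls[[tr]],
                   alternative = directions[[tr]])
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, trait = tr,
        mean_difference = mean(x[[tr]]) - mean(controls[[tr]]),
        p = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$bonferroni_factor <- nrow(out)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Odds ratio of cluster membership for top versus bottom score quintile
#'
#' Cuts the trait PRS at its empirical quintiles and forms the 2x2 table of
#' (top vs bottom quintile) against cluster membership; the odds ratio
#' carries a Wald 95% CI. Empty cells receive a 0.5 continuity correction
#' with a flag. A cumulative-logit alternative across all five quintiles is
#' available via `method = "logistic"` (OR per quintile step).
#'
#' @param trait_prs numeric trait score (n >= 5).
#' @param member logical/0-1 indicator of cluster membership.
#' @param method `"extremes"` (default) or `"logistic"`.
#' @return list with `or`, `ci`, `table` (for extremes), and
#'   `continuity_corrected` flag.
#' @export
quintile_or <- function(trait_prs, member, method = c("extremes",
                                                      "logistic")) {
  method <- match.arg(method)
  stopifnot(length(trait_prs) >= 5, length(member) == length(trait_prs))
  member <- as.integer(member)
  qs <- quantile(trait_prs, seq(0, 1, 0.2), names = FALSE)
  quintile <- cut(trait_prs, breaks = unique(qs), include.lowest = TRUE,
                  labels = FALSE)
  if (method == "logistic") {
    fit <- glm(member ~ quintile, family = binomial())
    cf <- summary(fit)$coefficients["quintile", ]
    return(list(or = exp(cf[["Estimate"]]),
                ci = exp(cf[["Estimate"]] +
                           c(-1, 1) * 1.96 * cf[["Std. Error"]]),
                method = "logistic"))
  }
  top <- quintile == max(quintile)
  bottom <- quintile == 1
  a <- sum(top & member == 1)
  b <- sum(top & member == 0)
  c_ <- sum(bottom & member == 1)
  d <- sum(bottom & member == 0)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("top", "bottom"),
                                c("member", "nonmember")))
  corrected <- any(tab == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or = or, ci = exp(log(or) + c(-1, 1) * 1.96 * se), table = tab,
       continuity_corrected = corrected, method = "extremes")
}

#' Per-cluster hazard ratios for vascular complications
#'
#' Cox proportional-hazards fits of time to macro- or microvascular
#' complication on cluster membership (categorical, referenced to the
#' largest cluster), optionally age-adjusted.
#'
#' @param labels cluster labels.
#' @param time event/censoring times (> 0).
#' @param event 0/1 event indicator.
#' @param age optional age vector; when supplied the fit is age-adjusted.
#' @return list with `hr` data frame (cluster, hr, lo, hi, p), `reference`
#'   cluster, and `ok` flag.
#' @export
complication_hazards <- function(labels, time, event, age = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 clusters", call. = FALSE)
  ref <- names(which.max(table(labels)))
  labels <- relevel(labels, ref = ref)
  dat <- data.frame(time = time, event = event, cluster = labels)
  fml <- survival::Surv(time, event) ~ cluster
  if (!is.null(age)) {
    dat$age <- age
    fml <- survival::Surv(time, event) ~ cluster + age
  }
  fit <- tryCatch(survival::coxph(fml, data = dat, ties = "efron"),
                  error = function(e) NULL)
  if (is.null(fit)) {
    return(list(hr = NULL, reference = ref, ok = FALSE,
                reason = "cox fit failed"))
  }
  sm <- summary(fit)$coefficients
  rows <- grep("^cluster", rownames(sm))
  hr <- data.frame(cluster = sub("^cluster", "", rownames(sm)[rows]),
                   hr = exp(sm[rows, "coef"]),
                   lo = exp(sm[rows, "coef"] - 1.96 * sm[rows, "se(coef)"]),
                   hi = exp(sm[rows, "coef"] + 1.96 * sm[rows, "se(coef)"]),
                   p = sm[rows, "Pr(>|z|)"],
                   stringsAsFactors = FALSE)
  ok <- all(is.finite(hr$hr)) && all(sm[rows, "se(coef)"] < 50)
  list(hr = hr, reference = ref, ok = ok)
}
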