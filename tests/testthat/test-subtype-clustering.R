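test_that("EM degenerate and well-separated cases behave as expected", {
  set.seed(901)
  X <- cbind(a = rnorm(200, 5, 2), b = rnorm(200, -3, 1))

  # k = 1: component mean is the sample mean, responsibilities all one
  m1 <- fit_mixture(X, 1, n_init = 1, seed = 1)
  expect_equal(as.numeric(m1$means), colMeans(X), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_true(all(m1$responsibilities == 1))

  # two components 10 SD apart: perfect recovery
  truth <- rep(1:2, each = 150)
  X2 <- cbind(x = rnorm(300, ifelse(truth == 1, 0, 10), 1),
              y = rnorm(300))
  m2 <- fit_mixture(X2, 2, n_init = 5, seed = 2)
  expect_equal(adjusted_rand_index(m2$labels, truth), 1)

  # log-likelihood is non-decreasing along EM iterations
  expect_true(all(diff(m2$ll_trace) > -1e-8 * abs(m2$loglik)))

  # responsibilities normalised; weights sum to one
  expect_equal(rowSums(m2$responsibilities), rep(1, 300), tolerance = 1e-9)
  expect_equal(sum(m2$weights), 1, tolerance = 1e-9)

  # information criteria follow their definitions
  expect_equal(m2$aic, 2 * m2$n_par - 2 * m2$loglik)
  expect_equal(m2$bic, m2$n_par * log(300) - 2 * m2$loglik)

  expect_error(fit_mixture(rbind(X2, NA), 2), "missing")
})

test_that("EM agrees with the mclust diagonal-model oracle", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(902)
  truth <- rep(1:3, each = 120)
  X <- cbind(x = rnorm(360, c(0, 4, 8)[truth], 1),
             y = rnorm(360, c(0, -4, 2)[truth], 1.5))
  m <- fit_mixture(X, 3, n_init = 10, seed = 3)
  Z <- scale(X)
  mc <- mclust::Mclust(Z, G = 3, modelNames = "VVI", verbose = FALSE)
  # same standardised data, same model family: log-likelihoods agree
  expect_equal(m$loglik, mc$loglik, tolerance = 1e-3)
  expect_gte(adjusted_rand_index(m$labels, mc$classification), 0.98)
})

test_that("elbow selection picks few components for single-Gaussian data", {
  set.seed(903)
  X <- matrix(rnorm(500 * 3), 500, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  sel <- select_k(X, k_range = 2:5, n_init = 4, seed = 4)
  expect_lte(sel$k, 2)
  # criterion curve bookkeeping: parameter counts increase with k
  expect_false(is.unsorted(sel$criteria$n_par))
  # override bypasses the rule
  sel5 <- select_k(X, k_range = 2:5, n_init = 2, seed = 4, override = 5)
  expect_equal(sel5$k, 5)
  expect_equal(sel5$rule, "override")
})

test_that("subtype labelling follows the mean-profile rules", {
  cfg <- sim_config(seed = 905, n_individuals = 4000)
  cc <- generate_cluster_cohort(cfg)
  fit <- fit_mixture(cc[, c("age", "bmi", "hba1c", "tg", "prs")], 5,
                     n_init = 8, seed = 6)
  lab <- label_clusters(fit, "integrated")
  expect_false(lab$unresolved)
  expect_setequal(lab$labels, c("MOD", "MARD", "SIRD", "IRD", "pSIDD"))
  # labelling is driven by component means, so it is invariant to the
  # arbitrary component order of a refit from a different seed
  fit2 <- fit_mixture(cc[, c("age", "bmi", "hba1c", "tg", "prs")], 5,
                      n_init = 8, seed = 16)
  lab2 <- label_clusters(fit2, "integrated")
  expect_setequal(lab2$labels, lab$labels)

  expect_error(label_clusters(fit_mixture(cc[, c("age", "bmi", "hba1c",
                                                 "tg", "prs")], 2,
                                          n_init = 2, seed = 2),
                              "integrated"),
               "5-component")

  # clinical variant labels MD by HDL
  cfgc <- sim_config(seed = 906, n_individuals = 3500,
                     cluster_params = cluster_params_clinical(),
                     complication_loghr = list(
                       macro = c(MOD = 0, MARD = 0, SIRD = 0, MD = 0,
                                 CUD = 0),
                       micro = c(MOD = 0, MARD = 0, SIRD = 0, MD = 0,
                                 CUD = 0),
                       macro_rate = 0.018, micro_rate = 0.037))
  ccc <- generate_cluster_cohort(cfgc)
  fitc <- fit_mixture(ccc[, c("age", "bmi", "hba1c", "tg", "hdl")], 5,
                      n_init = 8, seed = 7)
  labc <- label_clusters(fitc, "clinical")
  expect_setequal(labc$labels, c("MOD", "MARD", "SIRD", "MD", "CUD"))
})

test_that("PRS ANOVA reduces to the squared t in the two-group case", {
  set.seed(907)
  g <- rep(c("a", "b"), each = 60)
  x <- rnorm(120) + (g == "a") * 0.5
  an <- prs_anova(g, x)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p.value, tolerance = 1e-10)

  # power: 1 SD shifts at n=100/group are overwhelmingly significant
  g3 <- rep(c("a", "b", "c"), each = 100)
  x3 <- rnorm(300) + c(a = 0, b = 1, c = 2)[g3]
  expect_lt(prs_anova(g3, x3)$p, 0.001)

  expect_true(prs_anova(c("a", "a", "b"), rnorm(3))$degenerate)
})

test_that("trait-PRS contrasts use one-tailed Welch tests with Bonferroni", {
  set.seed(908)
  controls <- data.frame(fg_prs = rnorm(2000), beta_prs = rnorm(2000))
  members <- data.frame(
    cluster = rep(c("pSIDD", "MARD"), each = 500),
    fg_prs = c(rnorm(500, 0.30), rnorm(500, 0)),
    beta_prs = c(rnorm(500, 0.30), rnorm(500, 0)))
  out <- trait_prs_contrast(members, controls, c("fg_prs", "beta_prs"))
  expect_equal(unique(out$bonferroni_factor), 4) # 2 clusters x 2 traits
  psidd <- out[out$cluster == "pSIDD", ]
  expect_true(all(psidd$p_bonferroni < 0.001))
  expect_equal(psidd$mean_difference, rep(0.30, 2), tolerance = 0.15)

  # identical distributions: adjusted p near 1
  null_members <- data.frame(cluster = "x", fg_prs = rnorm(400),
                             beta_prs = rnorm(400))
  out0 <- trait_prs_contrast(null_members, controls,
                             c("fg_prs", "beta_prs"))
  expect_true(all(out0$p_bonferroni > 0.05))
})

test_that("quintile odds ratios match the hand-computed table", {
  # 500 ordered scores -> quintiles of 100; top has 50 members, bottom 25
  prs <- seq_len(500)
  member <- rep(0L, 500)
  member[sample(401:500, 50)] <- 1L
  member[sample(1:100, 25)] <- 1L
  r <- quintile_or(prs, member)
  expect_equal(r$or, (50 * 75) / (50 * 25))
  expect_false(r$continuity_corrected)

  # monotone relation gives OR > 1
  set.seed(909)
  p2 <- rnorm(2000)
  mem2 <- rbinom(2000, 1, plogis(-1 + 0.5 * p2))
  expect_gt(quintile_or(p2, mem2)$or, 1)
  expect_gt(quintile_or(p2, mem2, method = "logistic")$or, 1)

  # empty cell triggers continuity correction
  prs3 <- seq_len(50)
  mem3 <- as.integer(prs3 > 40)
  r3 <- quintile_or(prs3, mem3)
  expect_true(r3$continuity_corrected)
})

test_that("complication hazards recover generating log-hazards", {
  cfg <- sim_config(seed = 910, n_individuals = 5000)
  cc <- generate_cluster_cohort(cfg)
  hzm <- complication_hazards(cc$true_cluster, cc$macro_time,
                              cc$macro_event)
  expect_equal(hzm$reference, "pSIDD") # largest cluster is the reference
  # generating macrovascular log-HRs: MARD 0.5, MOD 0.4 vs pSIDD
  mard <- hzm$hr[hzm$hr$cluster == "MARD", ]
  expect_true(mard$lo < exp(0.5) && mard$hi > exp(0.5))
  mod <- hzm$hr[hzm$hr$cluster == "MOD", ]
  expect_true(mod$lo < exp(0.4) && mod$hi > exp(0.4))

  # age adjustment with age-independent hazards leaves HRs unchanged up to
  # the Monte-Carlo wobble induced by age-cluster collinearity
  hz_adj <- complication_hazards(cc$true_cluster, cc$macro_time,
                                 cc$macro_event, age = cc$age)
  expect_lt(max(abs(log(hz_adj$hr$hr) - log(hzm$hr$hr))), 0.3)
  expect_true(all(hz_adj$hr$lo < hzm$hr$hr & hzm$hr$hr < hz_adj$hr$hi |
                    abs(log(hz_adj$hr$hr) - log(hzm$hr$hr)) < 0.3))

  expect_error(complication_hazards(rep("a", 10), rexp(10), rbinom(10, 1,
                                                                   0.5)),
               "at least 2")
})
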