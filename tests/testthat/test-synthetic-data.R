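test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 5, n_individuals = 100, n_loci = 12,
                    ld_block_size = 3)
  g1 <- generate_genotypes(cfg)
  g2 <- generate_genotypes(cfg)
  expect_identical(g1, g2)
  ss1 <- generate_summary_stats(cfg, rep(0.1, 12), g1$variants)
  ss2 <- generate_summary_stats(cfg, rep(0.1, 12), g2$variants)
  expect_identical(ss1, ss2)
  cc1 <- generate_cluster_cohort(cfg)
  cc2 <- generate_cluster_cohort(cfg)
  expect_identical(cc1, cc2)
})

test_that("config validation rejects invalid correlation, SDs, proportions", {
  expect_error(sim_config(within_block_r2 = 1), "within_block_r2")
  expect_error(sim_config(prevalence_K = 0), "probabilities")
  cp <- cluster_params_integrated()
  cp$prop <- cp$prop * 2
  expect_error(sim_config(cluster_params = cp), "sum to 1")
  cp <- cluster_params_integrated()
  cp$sd_age[1] <- 0
  expect_error(sim_config(cluster_params = cp), "strictly positive")
})

test_that("LD blocks attain the configured allelic correlation", {
  # independence case
  cfg0 <- sim_config(seed = 11, n_individuals = 5000, n_loci = 20,
                     ld_block_size = 4, within_block_r2 = 0)
  g0 <- generate_genotypes(cfg0)
  expect_lt(mean_block_r2(g0$dosages, g0$variants$block), 0.02)
  expect_true(all(g0$dosages >= 0 & g0$dosages <= 2))

  # block size one: all mutually independent
  cfg1 <- sim_config(seed = 12, n_individuals = 5000, n_loci = 12,
                     ld_block_size = 1, within_block_r2 = 0.8)
  g1 <- generate_genotypes(cfg1)
  r <- cor(g1$dosages)
  expect_lt(max(r[upper.tri(r)]^2), 0.02)

  # calibrated case (Monte-Carlo check of the copula calibration)
  cfg2 <- sim_config(seed = 13, n_individuals = 10000, n_loci = 25,
                     ld_block_size = 5, within_block_r2 = 0.64)
  g2 <- generate_genotypes(cfg2)
  r2 <- mean_block_r2(g2$dosages, g2$variants$block)
  expect_gte(r2, 0.58)
  expect_lte(r2, 0.70)
})

test_that("summary statistics are calibrated under the null and scale with N", {
  cfg <- sim_config(seed = 21, n_loci = 1000)
  ss <- generate_summary_stats(cfg, rep(0, 1000))
  expect_lt(abs(mean(ss$P < 0.05) - 0.05), 0.02)

  # se -> 0 limit: huge discovery N makes beta_hat converge on truth
  cfg_big <- sim_config(seed = 22, n_loci = 50,
                        n_case_discovery = 5e8, n_control_discovery = 5e8)
  ss_big <- generate_summary_stats(cfg_big, rep(0.2, 50))
  expect_equal(ss_big$BETA, rep(0.2, 50), tolerance = 1e-3)

  # doubling N shrinks the median SE by 1/sqrt(2)
  cfg_a <- sim_config(seed = 23, n_loci = 400,
                      n_case_discovery = 5e4, n_control_discovery = 5e5)
  cfg_b <- sim_config(seed = 23, n_loci = 400,
                      n_case_discovery = 1e5, n_control_discovery = 1e6)
  se_a <- median(generate_summary_stats(cfg_a, rep(0, 400))$SE)
  se_b <- median(generate_summary_stats(cfg_b, rep(0, 400))$SE)
  expect_equal(se_b / se_a, 1 / sqrt(2), tolerance = 0.02)

  expect_error(
    generate_summary_stats(cfg, rep(0, 2),
                           data.frame(id = c("a", "b"), chrom = "1",
                                      pos = 1:2, effect_allele = "A",
                                      other_allele = "G", eaf = c(0, 0.5))),
    "strictly within")
})

test_that("cohort generator hits the design incidence and PRS effect", {
  # average the logistic refit over a few generator replicates to damp the
  # Monte-Carlo noise of a single draw
  ors <- numeric(0)
  incidences <- numeric(0)
  for (s in c(31, 131, 231)) {
    cfg <- sim_config(seed = s, n_individuals = 20000, n_loci = 60,
                      ld_block_size = 1)
    g <- generate_genotypes(cfg)
    w <- score_file(g$variants$id, g$variants$chrom, g$variants$pos,
                    g$variants$effect_allele, g$variants$other_allele,
                    weight = seq(-0.1, 0.1, length.out = 60))
    syn <- generate_cohort(cfg, g, w)
    incidences <- c(incidences, mean(syn$cohort$case_10yr))
    ors <- c(ors, exp(coef(glm(case_10yr ~ prs, data = syn$cohort,
                               family = binomial()))[["prs"]]))
  }
  co <- syn$cohort
  expect_true(all(co$time > 0))
  expect_true(all(co$event %in% 0:1))
  expect_lt(abs(mean(incidences) - 0.182), 0.01)
  expect_gte(mean(ors), 1.47)
  expect_lte(mean(ors), 1.67)

  # null PRS effect recovers OR 1
  cfg0 <- sim_config(seed = 32, n_individuals = 20000, n_loci = 60,
                     ld_block_size = 1, or_per_sd_prs = 1.0)
  syn0 <- generate_cohort(cfg0, g, w)
  or0 <- exp(coef(glm(case_10yr ~ prs, data = syn0$cohort,
                      family = binomial()))[["prs"]])
  expect_gte(or0, 0.95)
  expect_lte(or0, 1.05)

  # GDM group carries the configured PRS elevation
  gw <- syn$cohort[syn$cohort$female == 1, ]
  shift <- mean(gw$prs[gw$gdm == 1]) - mean(gw$prs[gw$gdm == 0])
  expect_equal(shift, 0.30, tolerance = 0.5)

  expect_error(
    generate_cohort(cfg, g, score_file("nope", "1", 1, "A", "G", 0.1)),
    "absent from genotypes")
})

test_that("cluster cohort matches its generating component profiles", {
  cfg <- sim_config(seed = 41, n_individuals = 5841)
  cc <- generate_cluster_cohort(cfg)
  cp <- cluster_params_integrated()
  for (j in seq_len(nrow(cp))) {
    sel <- cc$true_cluster == cp$label[j]
    n_j <- sum(sel)
    for (v in c("age", "bmi", "hba1c", "tg", "prs")) {
      mu <- cp[[paste0("mean_", v)]][j]
      se <- cp[[paste0("sd_", v)]][j] / sqrt(n_j)
      expect_lt(abs(mean(cc[[v]][sel]) - mu), 2.5 * se + 0.02)
    }
  }
  # equal complication hazards give Cox HR near 1
  cfg0 <- sim_config(seed = 42, n_individuals = 4000,
                     complication_loghr = list(
                       macro = c(MOD = 0, MARD = 0, SIRD = 0, IRD = 0,
                                 pSIDD = 0),
                       micro = c(MOD = 0, MARD = 0, SIRD = 0, IRD = 0,
                                 pSIDD = 0),
                       macro_rate = 0.018, micro_rate = 0.037))
  cc0 <- generate_cluster_cohort(cfg0)
  hz <- complication_hazards(cc0$true_cluster, cc0$macro_time,
                             cc0$macro_event)
  expect_true(all(hz$hr$lo < 1 & hz$hr$hi > 1))

  # single component: all labels identical
  cp1 <- cluster_params_integrated()[c(1, 1), ]
  cp1$prop <- c(0.5, 0.5)
  cfg1 <- sim_config(seed = 43, n_individuals = 100, cluster_params = cp1)
  cc1 <- generate_cluster_cohort(cfg1)
  expect_equal(length(unique(cc1$true_cluster)), 1)
})
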