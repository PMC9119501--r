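test_that("greedy clumping handles the canonical three-variant example", {
  set.seed(201)
  n <- 2000
  zA <- rnorm(n)
  zB <- sqrt(0.5) * zA + sqrt(0.5) * rnorm(n)
  zC <- rnorm(n)
  ref <- cbind(A = zA, B = zB, C = zC)
  ss <- data.frame(CHR = "1", POS = c(1e3, 2e3, 3e3), SNP = c("A", "B", "C"),
                   P = c(1e-8, 1e-6, 1e-4))
  expect_equal(ld_clump(ss, ref), c("A", "C"))
  expect_equal(ld_clump(ss, ref, p_cutoff = 1e-10), character(0))
  expect_equal(ld_clump(ss[1, ], ref), "A")
})

test_that("clumping equals the brute-force greedy oracle on random panels", {
  for (seed in 1:5) {
    pan <- make_panel(seed = seed, n = 400, m = 30, block = 5, r2 = 0.5)
    got <- ld_clump(pan$sumstats, pan$geno$dosages, r2_threshold = 0.1,
                    window_kb = 250)
    want <- clump_oracle(pan$sumstats, pan$geno$dosages, 0.1, 250)
    expect_identical(got, want)
  }
})

test_that("C+T scores are nested across thresholds", {
  pan <- make_panel(seed = 7, m = 24, block = 4)
  idx <- ld_clump(pan$sumstats, pan$geno$dosages)
  th <- c(min(pan$sumstats$P) * 0.1, 1e-4, 0.05, 1)
  scores <- build_ct_scores(pan$sumstats, idx, th)
  expect_equal(nrow(scores[[1]]), 0)            # below min p
  expect_equal(nrow(scores[[4]]), length(idx))  # threshold 1 takes all
  for (i in 1:3) {
    expect_true(all(scores[[i]]$rsID %in% scores[[i + 1]]$rsID))
  }
})

test_that("scoring matches hand arithmetic, including an allele swap", {
  d <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "v1"))
  s <- score_file("v1", "1", 100, "A", "G", 0.2)
  expect_equal(as.numeric(score_individuals(d, s)), c(0, 0.2, 0.4))

  s0 <- score_file(c("v1", "v2"), "1", c(1, 2), "A", "A", c(0, 0))
  d2 <- matrix(rbinom(20, 2, 0.5), 10, 2,
               dimnames = list(NULL, c("v1", "v2")))
  expect_equal(as.numeric(score_individuals(d2, s0)), rep(0, 10))

  # two-variant fixture: v2 is allele-swapped relative to the panel, so the
  # harmonised weight flips sign: raw = 0.3*d1 - 0.5*d2
  panel <- data.frame(id = c("v1", "v2"), effect_allele = c("A", "G"),
                      other_allele = c("G", "C"))
  sc <- score_file(c("v1", "v2"), "1", c(1, 2), c("A", "C"), c("G", "G"),
                   c(0.3, 0.5))
  h <- suppressMessages(harmonise_score(sc, panel, drop_ambiguous = FALSE))
  expect_equal(attr(h, "n_flipped"), 1L)
  dos <- matrix(c(2, 1, 0, 2), 2, 2, dimnames = list(NULL, c("v1", "v2")))
  expect_equal(as.numeric(score_individuals(dos, h)),
               c(0.3 * 2 - 0.5 * 0, 0.3 * 1 - 0.5 * 2))

  # strand-ambiguous entries are dropped by default
  amb <- score_file("v3", "1", 3, "A", "T", 0.1)
  panel3 <- data.frame(id = "v3", effect_allele = "A", other_allele = "T")
  expect_equal(nrow(suppressMessages(harmonise_score(amb, panel3))), 0)
})

test_that("PC residualisation standardises and flags degeneracies", {
  set.seed(202)
  n <- 300
  pcs <- matrix(rnorm(n * 10), n, 10)
  raw <- rnorm(n, 5, 2)
  z <- standardize_prs(raw, pcs)
  expect_equal(mean(z), 0, tolerance = 1e-8)
  expect_equal(sd(z), 1, tolerance = 1e-8)

  # orthogonal PCs leave the centred/scaled score essentially unchanged
  pcs_orth <- qr.Q(qr(cbind(1, pcs)))[, -1]
  raw_orth <- rnorm(n)
  raw_orth <- qr.resid(qr(cbind(1, pcs_orth)), raw_orth)
  z2 <- standardize_prs(raw_orth, pcs_orth)
  expect_equal(z2, (raw_orth - mean(raw_orth)) / sd(raw_orth),
               tolerance = 1e-8)

  # score exactly linear in the PCs: zero residual SD is an error
  expect_error(standardize_prs(2 + pcs %*% rep(1, 10), pcs), "residual SD")

  # collinear PC columns dropped with a warning
  expect_warning(standardize_prs(raw, cbind(pcs, pcs[, 1])), "collinear")
})

test_that("rank AUC equals pairwise brute force and pROC", {
  set.seed(203)
  y <- rbinom(300, 1, 0.4)
  s <- rnorm(300) + 0.8 * y
  s[1:20] <- round(s[1:20], 1)  # inject ties
  ev <- evaluate_prs(s, y, NULL)
  brute <- {
    pos <- s[y == 1]
    neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  expect_equal(ev$auc_full, brute, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(ev$auc_full,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("PRS evaluation behaves at its null and separated limits", {
  set.seed(204)
  n <- 20000
  y <- rbinom(n, 1, 0.2)
  z_null <- rnorm(n)
  covs <- data.frame(age = rnorm(n), female = rbinom(n, 1, 0.5))
  ev0 <- evaluate_prs(z_null, y, covs)
  expect_lt(abs(ev0$incremental_auc), 0.01)

  sep <- ifelse(y == 1, 1, -1) + rnorm(n, 0, 1e-6)
  evs <- suppressWarnings(evaluate_prs(sep, y, NULL))
  expect_equal(evs$auc_full, 1, tolerance = 1e-6)

  expect_error(evaluate_prs(z_null, rep(1, n)), "single class")
})

test_that("liability-scale conversion is zero at zero and increasing", {
  expect_equal(liability_r2(0, 0.136, 0.3), 0)
  grid <- seq(0, 0.5, by = 0.05)
  vals <- vapply(grid, liability_r2, numeric(1), K = 0.136, P = 0.3)
  expect_false(is.unsorted(vals))
  expect_true(all(diff(vals) > 0))
})

test_that("score mixing picks sensible weights on the grid", {
  set.seed(205)
  n <- 4000
  z_signal <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * z_signal))
  noise <- rnorm(n)

  tie <- combine_prs(z_signal, z_signal, y)
  expect_equal(tie$alpha, 0.5)
  expect_false(is.na(tie$note))

  mix <- combine_prs(z_signal, noise, y)
  expect_gte(mix$alpha, 0.8)
  expect_true(mix$alpha %in% seq(0, 1, by = 0.1))
})
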