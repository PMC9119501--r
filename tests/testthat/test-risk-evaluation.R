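test_that("categorical NRI matches direct counting", {
  # 10 cases: 3 up, 1 down; 90 noncases: 2 up, 5 down -> 0.2 + 3/90
  oc <- rep("low", 100)
  nc <- rep("low", 100)
  y <- c(rep(1, 10), rep(0, 90))
  nc[1:3] <- "high"                      # cases up
  oc[4] <- "high"; nc[4] <- "low"        # case down
  nc[11:12] <- "high"                    # noncases up
  oc[13:17] <- "high"; nc[13:17] <- "low" # noncases down
  r <- categorical_nri(oc, nc, y)
  expect_equal(r$nri, 0.2 + 3 / 90, tolerance = 1e-12)
  expect_equal(r$nri, nri_oracle(oc, nc, y), tolerance = 1e-12)
  expect_equal(sum(r$counts[1, c("up", "down", "unchanged")]), 10)
  expect_equal(sum(r$counts[2, c("up", "down", "unchanged")]), 90)

  # identity, maximum, antisymmetry, oracle on random tables
  expect_equal(categorical_nri(oc, oc, y)$nri, 0)
  all_up <- ifelse(y == 1, "high", "low")
  all_base <- ifelse(y == 1, "low", "high")
  expect_equal(categorical_nri(all_base, all_up, y)$nri, 2)
  set.seed(501)
  for (i in 1:20) {
    o <- sample(c("low", "high"), 50, replace = TRUE)
    n <- sample(c("low", "high"), 50, replace = TRUE)
    yy <- sample(0:1, 50, replace = TRUE, prob = c(0.7, 0.3))
    if (length(unique(yy)) < 2) next
    expect_equal(categorical_nri(o, n, yy)$nri, nri_oracle(o, n, yy),
                 tolerance = 1e-12)
    expect_equal(categorical_nri(o, n, yy)$nri,
                 -categorical_nri(n, o, yy)$nri, tolerance = 1e-12)
  }

  # single-status data flags an undefined component
  r1 <- categorical_nri(oc[1:10], nc[1:10], rep(1, 10))
  expect_true(r1$undefined[["noncase"]])
})

test_that("continuous NRI counts any risk movement", {
  old <- c(0.1, 0.2, 0.3, 0.4, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  new <- c(0.2, 0.3, 0.4, 0.3, 0.05, 0.1, 0.2, 0.5, 0.4, 0.3)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  # cases: 3 up 1 down of 4; noncases: 4 down 2... construct: up for
  # noncases is index 8 only -> (3-1)/4 + (5-1)/6
  r <- continuous_nri(old, new, y)
  expect_equal(r$nri, (3 - 1) / 4 + (5 - 1) / 6, tolerance = 1e-12)
  expect_equal(continuous_nri(old, old, y)$nri, 0)
  inc <- ifelse(y == 1, old + 0.01, old - 0.01)
  expect_equal(continuous_nri(old, inc, y)$nri, 2)
})

test_that("bootstrap intervals are deterministic and degenerate correctly", {
  x <- rnorm(50)
  const <- bootstrap_ci(function(i) 1.5, n = 50, B = 100, seed = 9)
  expect_equal(const$lo, 1.5)
  expect_equal(const$hi, 1.5)
  expect_equal(const$point, 1.5)

  m1 <- bootstrap_ci(function(i) mean(x[i]), n = 50, B = 200, seed = 42)
  m2 <- bootstrap_ci(function(i) mean(x[i]), n = 50, B = 200, seed = 42)
  expect_identical(m1, m2)
  expect_lt(m1$lo, m1$point)
  expect_gt(m1$hi, m1$point)
  expect_error(bootstrap_ci(function(i) 1, n = 10, B = 1), "B >= 2")
})

test_that("concordance equals brute-force pair counting", {
  expect_equal(c_index(c(0.8, 0.9, 0.1), c(1, 2, 3), c(1, 1, 0))$c_index,
               2 / 3)
  # perfect anti-ranking with no censoring
  expect_equal(c_index(c(3, 2, 1), 1:3, rep(1, 3))$c_index, 1)
  # constant risk: everything ties at one half
  expect_equal(c_index(rep(0.4, 10), 1:10, rep(1, 10))$c_index, 0.5)
  # no comparable pairs
  expect_true(c_index(c(0.1, 0.9), c(1, 2), c(0, 0))$undefined)

  set.seed(502)
  for (i in 1:5) {
    n <- 150
    risk <- round(runif(n), 2)          # induce risk ties
    time <- round(rexp(n, 0.1), 1) + 0.1
    event <- rbinom(n, 1, 0.6)
    expect_equal(c_index(risk, time, event)$c_index,
                 c_index_oracle(risk, time, event), tolerance = 1e-12)
  }
})

test_that("subgroup report partitions the cohort and matches the sweep", {
  set.seed(503)
  n <- 400
  co <- data.frame(age = runif(n, 25, 60), female = rbinom(n, 1, 0.5))
  oc <- sample(c("low", "high"), n, replace = TRUE)
  nc <- sample(c("low", "high"), n, replace = TRUE)
  y <- rbinom(n, 1, 0.3)
  rep_tab <- subgroup_report(co, function(sel) {
    categorical_nri(oc[sel], nc[sel], y[sel])
  }, age_cut = 40)
  expect_equal(sum(rep_tab$n[rep_tab$stratum != "overall"]), n)
  expect_equal(rep_tab$n[rep_tab$stratum == "overall"], n)

  sw <- age_threshold_sweep(co, oc, nc, y, cuts = c(35, 40, 45))
  at40 <- sw[sw$cut == 40, ]
  young_sel <- co$age < 40
  expect_equal(at40$nri[at40$stratum == "young"],
               categorical_nri(oc[young_sel], nc[young_sel],
                               y[young_sel])$nri)
  # degenerate stratum flagged for a single-age cohort
  co1 <- data.frame(age = rep(30, 20), female = rbinom(20, 1, 0.5))
  sw1 <- age_threshold_sweep(co1, oc[1:20], nc[1:20], y[1:20],
                             cuts = c(30, 40))
  expect_true(any(sw1$degenerate))
})

test_that("reclassification descriptives summarise by direction", {
  co <- data.frame(age = c(30, 40, 50, 60), bmi = c(22, 30, 26, 28),
                   prs = c(1, -1, 0, 2), q = c(0.05, 0.2, 0.1, 0.3),
                   fpg = c(4.5, 5.5, 5.0, 6.0), hba1c = c(38, 42, 40, 44))
  oc <- c("low", "high", "low", "high")
  nc <- c("high", "low", "low", "high")
  r <- reclassified_characteristics(co, oc, nc)
  expect_setequal(r$table$direction, c("up", "down", "unchanged"))
  expect_equal(r$table$age[r$table$direction == "up"], 30)
  expect_named(r$prs_correlations, c("q", "fpg", "hba1c"))
})
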