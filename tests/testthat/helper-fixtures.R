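# Shared fixture builders; everything is generated in code at test time.

# Small genotype panel + matching summary stats with a handful of causal loci.
make_panel <- function(seed = 1, n = 500, m = 30, block = 3, r2 = 0.3) {
  cfg <- sim_config(seed = seed, n_individuals = n, n_loci = m,
                    ld_block_size = block, within_block_r2 = r2)
  g <- generate_genotypes(cfg)
  beta <- rep(0, m)
  beta[seq(1, m, by = block)] <- 0.15
  ss <- generate_summary_stats(cfg, beta, g$variants)
  list(cfg = cfg, geno = g, beta = beta, sumstats = ss)
}

# Reference-free brute-force greedy clumping: re-applies the definition from
# scratch at every step (independent of the package's single-pass loop).
clump_oracle <- function(summary, reference, r2_threshold, window_kb) {
  summary <- summary[order(summary$P, summary$CHR, summary$POS), ]
  chosen <- character(0)
  removed <- character(0)
  repeat {
    remaining <- summary[!summary$SNP %in% c(chosen, removed), , drop = FALSE]
    if (nrow(remaining) == 0) break
    idx <- remaining$SNP[1]
    chosen <- c(chosen, idx)
    row_i <- summary[summary$SNP == idx, ]
    for (j in remaining$SNP[-1]) {
      row_j <- summary[summary$SNP == j, ]
      if (row_j$CHR == row_i$CHR &&
          abs(row_j$POS - row_i$POS) <= window_kb * 1000) {
        r2 <- suppressWarnings(cor(reference[, idx], reference[, j]))^2
        if (!is.na(r2) && r2 > r2_threshold) removed <- c(removed, j)
      }
    }
  }
  chosen
}

# O(n^2) pairwise Harrell's C, the concordance oracle. A pair is comparable
# when one individual has an observed event before the other's follow-up
# ends; an event tied in time with a censoring is comparable (the censored
# individual is known to survive past the event), while two events tied in
# time are not.
c_index_oracle <- function(risk, time, event) {
  num <- 0
  den <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- event[i] == 1 &&
        (time[i] < time[j] ||
           (time[i] == time[j] && event[j] == 0))
      if (comparable) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Direct-counting NRI oracle.
nri_oracle <- function(old_class, new_class, outcome) {
  up <- old_class == "low" & new_class == "high"
  down <- old_class == "high" & new_class == "low"
  mean(up[outcome == 1]) - mean(down[outcome == 1]) +
    mean(down[outcome == 0]) - mean(up[outcome == 0])
}

# Logistic 10-year case-status data generated under the IRT model itself.
make_irt_data <- function(seed, n_per_sex = 2000, b_prs = log(1.57),
                          b_int = 0, b_q = 1) {
  set.seed(seed)
  n <- 2 * n_per_sex
  female <- rep(c(0, 1), each = n_per_sex)
  q <- plogis(rnorm(n, -2.3, 0.8))
  z <- rnorm(n)
  l <- qlogis(q)
  p <- plogis(-0.3 + b_q * l + b_prs * z + b_int * z * l)
  case <- rbinom(n, 1, p)
  data.frame(q = q, prs = z, female = female, case_10yr = case)
}
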