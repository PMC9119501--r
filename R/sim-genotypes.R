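#' @keywords internal
#' Run code under a temporary RNG seed, restoring session RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Bivariate standard-normal lower orthant P(X < h, Y < k) for latent
# correlation rho, by one-dimensional quadrature.
pnorm2 <- function(h, k, rho) {
  if (abs(rho) < 1e-12) return(pnorm(h) * pnorm(k))
  f <- function(x) dnorm(x) * pnorm((k - rho * x) / sqrt(1 - rho^2))
  integrate(f, -Inf, h, rel.tol = 1e-10)$value
}

# Pearson (phi) correlation of two indicators 1{Z1 < qnorm(f)}, 1{Z2 < qnorm(f)}
# when (Z1, Z2) are standard normal with correlation rho.
phi_from_rho <- function(rho, f) {
  t <- qnorm(f)
  (pnorm2(t, t, rho) - f^2) / (f * (1 - f))
}

# Latent correlation required so that thresholded haplotypes (and hence
# dosages) attain a target allelic correlation at effect-allele frequency f.
calibrate_latent_rho <- function(target_r, f) {
  if (target_r <= 0) return(0)
  uniroot(function(rho) phi_from_rho(rho, f) - target_r,
          interval = c(1e-6, 1 - 1e-6), tol = 1e-8)$root
}

#' Generate LD-structured genotype dosages
#'
#' Simulates biallelic genotype dosages for `n_individuals` x `n_loci`
#' variants organised in LD blocks. Each haplotype is a latent
#' multivariate-normal draw with equicorrelation within a block, thresholded
#' at the variant's effect-allele frequency; dosage is the sum of two
#' independent haplotypes, so values lie in `{0, 1, 2}` and the pairwise
#' allelic correlation within a block is calibrated to
#' `sqrt(within_block_r2)`. Blocks are mutually independent and placed 1 Mb
#' apart so that clumping windows treat them as separate loci.
#'
#' @param config a [sim_config()].
#' @return list with `dosages` (individuals x variants matrix, dimnames set)
#'   and `variants` (data frame: id, chrom, pos, effect/other allele, eaf,
#'   block).
#' @examples
#' g <- generate_genotypes(sim_config(seed = 1, n_individuals = 50, n_loci = 10))
#' dim(g$dosages)
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_loci
  bs <- config$ld_block_size
  n_block <- ceiling(m / bs)
  block <- rep(seq_len(n_block), each = bs)[seq_len(m)]
  target_r <- sqrt(config$within_block_r2)

  with_seed(config$seed, {
    # One EAF per block: variants in tight LD share a frequency, and unequal
    # frequencies would cap the attainable allelic correlation below target.
    eaf_block <- runif(n_block, config$eaf_range[1], config$eaf_range[2])
    eaf <- eaf_block[block]
    dos <- matrix(0L, n, m)
    for (b in seq_len(n_block)) {
      idx <- which(block == b)
      k <- length(idx)
      rho <- if (k > 1) calibrate_latent_rho(target_r, eaf_block[b]) else 0
      for (hap in 1:2) {
        if (rho > 0) {
          w <- rnorm(n)
          z <- sqrt(rho) * w + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
        } else {
          z <- matrix(rnorm(n * k), n, k)
        }
        al <- sweep(z, 2, qnorm(eaf[idx]), `<`)
        dos[, idx] <- dos[, idx] + al
      }
    }
    ids <- sprintf("var%04d", seq_len(m))
    pos <- (block - 1L) * 1000000L + (seq_len(m) - (block - 1L) * bs) * 10000L
    variants <- data.frame(id = ids, chrom = "1", pos = pos,
                           effect_allele = "A", other_allele = "G",
                           eaf = eaf, block = block,
                           stringsAsFactors = FALSE)
    dimnames(dos) <- list(sprintf("id%05d", seq_len(n)), ids)
    list(dosages = dos, variants = variants)
  })
}

#' Empirical pairwise r-squared within LD blocks
#'
#' Convenience summary used to check the generator: mean squared Pearson
#' correlation over all within-block variant pairs.
#'
#' @param dosages dosage matrix.
#' @param block integer block index per variant.
#' @return mean within-block r-squared (NA if no pairs exist).
#' @export
mean_block_r2 <- function(dosages, block) {
  vals <- c()
  for (b in unique(block)) {
    idx <- which(block == b)
    if (length(idx) < 2) next
    r <- cor(dosages[, idx])
    vals <- c(vals, r[upper.tri(r)]^2)
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}
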