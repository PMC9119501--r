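#' Simulate discovery GWAS summary statistics
#'
#' Emulates a large case-control discovery scan: for each variant the
#' estimated log odds ratio is drawn around its true value with the standard
#' additive-logistic standard error
#' \deqn{se = 1 / \sqrt{2 f (1-f) N \phi (1-\phi)}}
#' where `f` is the effect-allele frequency, `N` the total discovery sample
#' size and `phi` the case fraction; the p-value is the two-sided Wald test.
#'
#' @param config a [sim_config()]; supplies discovery sample sizes, the EAF
#'   range and the seed.
#' @param true_betas numeric vector of true per-allele log odds ratios, one
#'   per variant.
#' @param variants optional variant metadata from [generate_genotypes()]; when
#'   omitted, EAFs are drawn from `config$eaf_range` and placeholder
#'   coordinates are assigned.
#' @return data frame with columns CHR, POS, SNP, EA, OA, EAF, BETA, SE, P.
#' @examples
#' ss <- generate_summary_stats(sim_config(seed = 1, n_loci = 5), rep(0, 5))
#' ss$P
#' @export
generate_summary_stats <- function(config, true_betas, variants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  m <- length(true_betas)
  if (is.null(variants)) {
    with_seed(config$seed + 1L, {
      eaf <- runif(m, config$eaf_range[1], config$eaf_range[2])
    })
    variants <- data.frame(id = sprintf("var%04d", seq_len(m)),
                           chrom = "1", pos = seq_len(m) * 10000L,
                           effect_allele = "A", other_allele = "G",
                           eaf = eaf, stringsAsFactors = FALSE)
  }
  if (nrow(variants) != m) {
    stop("need exactly one true beta per variant", call. = FALSE)
  }
  if (any(variants$eaf <= 0) || any(variants$eaf >= 1)) {
    stop("effect-allele frequencies must lie strictly within (0,1)",
         call. = FALSE)
  }
  N <- config$n_case_discovery + config$n_control_discovery
  phi <- config$n_case_discovery / N
  se <- 1 / sqrt(2 * variants$eaf * (1 - variants$eaf) * N * phi * (1 - phi))
  with_seed(config$seed + 2L, {
    beta_hat <- rnorm(m, mean = true_betas, sd = se)
  })
  z <- beta_hat / se
  data.frame(CHR = variants$chrom, POS = variants$pos, SNP = variants$id,
             EA = variants$effect_allele, OA = variants$other_allele,
             EAF = variants$eaf, BETA = beta_hat, SE = se,
             P = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
}
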