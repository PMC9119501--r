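# prsirt

Polygenic and clinical integrated risk modelling for type 2 diabetes (T2D).

British South Asians carry a high burden of T2D yet are underrepresented in
the European-ancestry GWAS from which most polygenic risk scores (PRS) are
built. `prsirt` implements, as reusable and tested R functions, the
computational chain needed to study that gap in a Pakistani/Bangladeshi-like
target population:

1. **Locus transferability** — test whether discovery-GWAS loci replicate in
   a target sample, compute the power-based expected replication count
   (`power_i` from the Wald SE approximation
   `se ≈ 1/√(2f(1−f)·N·φ(1−φ))`), and compare observed vs expected with an
   exact one-sided binomial test.
2. **C+T polygenic scores** — greedy LD clumping (r² threshold, ascending
   p), p-value thresholding over a grid, PGS-Catalog-style scoring with
   allele harmonisation, principal-component residualisation to a mean-0/SD-1
   score, and evaluation by AUC, incremental AUC, liability-scale R²
   (case-control ascertainment-adjusted), and OR per SD.
3. **Clinical risk** — a QDiabetes-style 10-year risk engine
   `risk = 1 − S0^exp(η)` over pluggable coefficient sets (models A/B/C),
   with the standard inclusion filters (age 25–84, no prior disease,
   HbA1c ≤ 48 mmol/mol, FPG ≤ 7 mmol/L).
4. **Integrated risk tool (IRT)** — sex-stratified logistic model of 10-year
   case status on PRS, logit clinical risk, and their interaction; clinical
   odds are multiplied by the centred PRS-conditional odds and re-expressed
   as a probability, dichotomised at 10%.
5. **Evaluation** — categorical and continuous net reclassification
   improvement (NRI = P(up|case) − P(down|case) + P(down|noncase) −
   P(up|noncase)), percentile-bootstrap CIs, Harrell's C, age-by-sex
   subgroups and an age-cutoff sweep.
6. **Post-GDM progression** — greedy age/BMI-matched controls, group
   contrasts, and Cox hazard ratios per SD of PRS.
7. **Subtype clustering** — latent profile analysis (diagonal-covariance
   Gaussian mixture fitted by EM), BIC-elbow selection of the number of
   components, rule-based subtype labels (MOD/MARD/SIRD/MD/CUD and
   MOD/MARD/SIRD/IRD/pSIDD), PRS ANOVA across clusters, trait-PRS contrasts,
   quintile odds ratios, and complication hazards.

A first-class synthetic-data module (`sim_config()`, `generate_genotypes()`,
`generate_summary_stats()`, `generate_cohort()`,
`generate_cluster_cohort()`) generates genotypes with calibrated LD blocks,
discovery summary statistics, and cohorts with ~13.6% background prevalence,
an OR per SD of PRS of 1.57, 18.2% ten-year incidence, a GDM subcohort with
elevated PRS, and a five-component subtype mixture — so every stage runs and
is testable without access to any individual-level study data.

## Worked example

```r
library(prsirt)

# the published-style worked example: 76 of 338 loci replicate where 30%
# were expected given power
transfer_test(76, 0.30, 338)
#> [1] 0.001232566

# a fully synthetic study, end to end
cfg <- pipeline_config(seed = 11, out_dir = "run1",
                       n_individuals = 4000, n_loci = 200, B = 100)
res <- run_pipeline(cfg, quiet = TRUE)
round(res$evaluate$nri_categorical, 3)
#> [1] 0.091
round(c(res$evaluate$c_index_clinical, res$evaluate$c_index_irt), 3)
#> [1] 0.638 0.669
res$cluster$selected_k
#> [1] 5
```

The pipeline writes `summary_stats.tsv`, `cohort.csv`, `prs_score.txt`
(PGS-Catalog dialect), `irt_model.json`, per-stage CSV tables (each with a
`# seed=... config_md5=...` header), and a consolidated `results.json` under
the output directory. In the run above, adding the PRS to the clinical risk
score reclassifies a net 9.1% of individuals correctly at the 10% risk
threshold and lifts the concordance index from 0.638 to 0.669; the
information-criterion elbow recovers the five generating disease subtypes.

A thin command-line wrapper is installed at `inst/cli/prsirt.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/prsirt.R", package="prsirt"))') \
    all --seed 11 --out run1
```

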