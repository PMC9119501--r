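Package: prsirt
Title: Polygenic and Clinical Integrated Risk Modelling for Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing cross-ancestry transferability of type 2
    diabetes GWAS loci, constructing clumping-and-thresholding polygenic risk
    scores, combining a polygenic score with a QDiabetes-style 10-year
    clinical risk engine into an integrated risk tool, evaluating risk tools
    by net reclassification and concordance, analysing progression to type 2
    diabetes after gestational diabetes, and latent-profile subtyping of
    diabetes at diagnosis. Includes a seeded synthetic-data generator that
    emulates the cohort, genotype, and summary-statistic structure these
    analyses assume, so the whole pipeline runs and is testable without any
    individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    pROC,
    mclust,
    optparse
Config/testthat/edition: 3
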