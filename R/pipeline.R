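#' Pipeline configuration
#'
#' Validates and completes the configuration driving [run_pipeline()].
#' Unknown keys are rejected. The resolved configuration is written next to
#' the outputs of every run.
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @param stages character vector of stages to run, in dependency order,
#'   from: simulate, transfer, prs, clinrisk, irt, evaluate, gdm, cluster.
#' @param n_individuals,n_loci synthetic cohort dimensions.
#' @param alpha replication significance level.
#' @param r2_threshold clumping r-squared threshold.
#' @param thresholds C+T p-value threshold grid.
#' @param K population prevalence for liability conversions.
#' @param risk_threshold high/low risk cutoff.
#' @param age_cut age subgroup threshold.
#' @param B bootstrap replicates for NRI CIs.
#' @param k_range candidate cluster counts.
#' @param n_init EM restarts per mixture fit.
#' @param ... rejected; catches unknown keys.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("prsirt_run_"),
                            stages = c("simulate", "transfer", "prs",
                                       "clinrisk", "irt", "evaluate",
                                       "gdm", "cluster"),
                            n_individuals = 5000L, n_loci = 300L,
                            alpha = 0.05, r2_threshold = 0.1,
                            thresholds = c(5e-8, 1e-6, 1e-5, 1e-4, 1e-3),
                            K = 0.136, risk_threshold = 0.10, age_cut = 40,
                            B = 200L, k_range = 2:8, n_init = 8L, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  known <- c("simulate", "transfer", "prs", "clinrisk", "irt", "evaluate",
             "gdm", "cluster")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 stages = stages, n_individuals = as.integer(n_individuals),
                 n_loci = as.integer(n_loci), alpha = alpha,
                 r2_threshold = r2_threshold, thresholds = sort(thresholds),
                 K = K, risk_threshold = risk_threshold, age_cut = age_cut,
                 B = as.integer(B), k_range = k_range,
                 n_init = as.integer(n_init)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys must match [pipeline_config()] arguments.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Write a table with a reproducibility header comment.
write_result_table <- function(x, path, seed, config_md5) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config_md5=%s", seed, config_md5), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline end to end
#'
#' Executes the selected stages in dependency order on a synthetic study:
#' simulate genotypes/summary statistics/cohort; assess locus
#' transferability; construct and evaluate the C+T polygenic score; compute
#' clinical 10-year risks; fit and apply the integrated risk tool; evaluate
#' reclassification and concordance; analyse post-GDM progression; and run
#' the subtype clustering. Results are written as CSV/JSON under
#' `config$out_dir` together with the resolved configuration; numeric
#' outputs are deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a named list of per-stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  cfg_md5 <- unname(tools::md5sum(cfg_path))
  say <- function(...) if (!quiet) message(...)
  res <- list()
  state <- new.env(parent = emptyenv())

  need <- function(stage, what) {
    if (is.null(state[[what]])) {
      stop(sprintf("stage '%s' requires outputs of a stage that was not run",
                   stage), call. = FALSE)
    }
    state[[what]]
  }

  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    say("stage: ", stage)
    out <- tryCatch(fn(), error = function(e) {
      stop(sprintf(
        "stage '%s' failed: %s\nreproduce with run_pipeline(pipeline_config(seed = %d, stages = \"%s\", ...))",
        stage, conditionMessage(e), config$seed, stage), call. = FALSE)
    })
    res[[stage]] <<- out
    out
  }

  run_stage("simulate", function() {
    scfg <- sim_config(seed = config$seed,
                       n_individuals = config$n_individuals,
                       n_loci = config$n_loci,
                       prevalence_K = config$K)
    geno <- generate_genotypes(scfg)
    blocks <- unique(geno$variants$block)
    true_beta <- rep(0, config$n_loci)
    with_seed(config$seed + 10L, {
      causal <- vapply(blocks, function(b) {
        which(geno$variants$block == b)[1]
      }, integer(1))
      true_beta[causal] <- rnorm(length(causal), 0, 0.12)
    })
    ss <- generate_summary_stats(scfg, true_beta, geno$variants)
    causal_idx <- which(true_beta != 0)
    wts <- score_file(geno$variants$id[causal_idx],
                      geno$variants$chrom[causal_idx],
                      geno$variants$pos[causal_idx],
                      geno$variants$effect_allele[causal_idx],
                      geno$variants$other_allele[causal_idx],
                      true_beta[causal_idx], source = "generating-truth")
    syn <- generate_cohort(scfg, geno, wts)
    write_summary_stats(ss, file.path(config$out_dir, "summary_stats.tsv"))
    write_cohort(syn$cohort, file.path(config$out_dir, "cohort.csv"))
    jsonlite::write_json(syn$truth, file.path(config$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    state$scfg <- scfg
    state$geno <- geno
    state$sumstats <- ss
    state$true_beta <- true_beta
    state$syn <- syn
    list(n = nrow(syn$cohort), n_loci = config$n_loci,
         case_fraction = mean(syn$cohort$case_10yr))
  })

  run_stage("transfer", function() {
    ss <- need("transfer", "sumstats")
    syn <- need("transfer", "syn")
    geno <- need("transfer", "geno")
    sig <- ss[ss$P < 1e-3, , drop = FALSE]
    y <- syn$cohort$case_10yr
    n_case <- sum(y)
    n_ctrl <- sum(1 - y)
    rows <- lapply(seq_len(nrow(sig)), function(i) {
      d <- geno$dosages[, sig$SNP[i]]
      a <- assoc_test(d, y)
      data.frame(SNP = sig$SNP[i], beta_discovery = sig$BETA[i],
                 p_discovery = sig$P[i], eaf_target = mean(d) / 2,
                 beta_target = a$beta, se_target = a$se, p_target = a$p,
                 ok = a$ok, stringsAsFactors = FALSE)
    })
    loci <- do.call(rbind, rows)
    loci <- loci[loci$ok & loci$eaf_target > 0 & loci$eaf_target < 1, ,
                 drop = FALSE]
    loci$power <- replication_power(loci$beta_discovery, loci$eaf_target,
                                    n_case, n_ctrl, alpha = config$alpha)
    cls <- classify_transferable(loci, alpha = config$alpha)
    exp_rep <- expected_replications(loci$power)
    p_trans <- transfer_test(cls$n_transferable,
                             exp_rep$expected_proportion, nrow(loci))
    write_result_table(cls$loci, file.path(config$out_dir, "loci.csv"),
                       config$seed, cfg_md5)
    list(n_loci = nrow(loci), n_transferable = cls$n_transferable,
         pct_transferable = cls$pct_transferable,
         n_bonferroni = cls$n_bonferroni,
         expected_count = exp_rep$expected_count,
         expected_proportion = exp_rep$expected_proportion,
         p_transfer = p_trans)
  })

  run_stage("prs", function() {
    ss <- need("prs", "sumstats")
    geno <- need("prs", "geno")
    syn <- need("prs", "syn")
    idx <- ld_clump(ss, geno$dosages, r2_threshold = config$r2_threshold,
                    p_cutoff = max(config$thresholds))
    scores <- build_ct_scores(ss, idx, config$thresholds)
    pcs <- as.matrix(syn$cohort[, paste0("pc", 1:10)])
    y <- syn$cohort$case_10yr
    n <- length(y)
    sel <- with_seed(config$seed + 20L, {
      sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.5, 0.5))
    })
    evals <- lapply(scores, function(sc) {
      if (nrow(sc) == 0) return(NULL)
      raw <- score_individuals(geno$dosages, sc)
      z <- standardize_prs(raw, pcs)
      if (length(unique(y[sel])) < 2) return(NULL)
      ev <- evaluate_prs(z[sel], y[sel],
                         data.frame(age = syn$cohort$age[sel],
                                    female = syn$cohort$female[sel],
                                    pcs[sel, ]), K = config$K)
      list(z = z, eval = ev)
    })
    keep <- !vapply(evals, is.null, logical(1))
    if (!any(keep)) stop("no non-empty C+T score on the threshold grid")
    inc <- vapply(evals[keep], function(e) e$eval$incremental_auc,
                  numeric(1))
    best_name <- names(which.max(inc))
    best <- evals[[best_name]]
    final <- evaluate_prs(best$z[!sel], y[!sel],
                          data.frame(age = syn$cohort$age[!sel],
                                     female = syn$cohort$female[!sel],
                                     pcs[!sel, ]), K = config$K)
    state$prs_z <- best$z
    write_score_file(scores[[best_name]],
                     file.path(config$out_dir, "prs_score.txt"))
    list(n_index = length(idx), best_threshold = best_name,
         n_variants = nrow(scores[[best_name]]),
         selection_incremental_auc = unname(max(inc)),
         test_eval = final)
  })

  run_stage("clinrisk", function() {
    syn <- need("clinrisk", "syn")
    spec <- default_risk_spec("A")
    inc <- apply_inclusion_criteria(syn$cohort)
    r <- risk_10yr(inc, spec)
    inc$q <- pmin(pmax(r$risk, 1e-6), 1 - 1e-6)
    state$analysis_cohort <- inc[!r$failed, , drop = FALSE]
    list(n_included = nrow(inc), n_failed = sum(r$failed),
         mean_risk = mean(inc$q, na.rm = TRUE),
         pct_high = 100 * mean(inc$q > config$risk_threshold, na.rm = TRUE))
  })

  run_stage("irt", function() {
    ac <- need("irt", "analysis_cohort")
    if (!is.null(state$prs_z)) {
      m <- match(ac$id, rownames(need("irt", "geno")$dosages))
      ac$prs <- state$prs_z[m]
    }
    model <- fit_irt(ac)
    ac$irt_risk <- predict(model, ac)
    state$analysis_cohort <- ac
    state$irt_model <- model
    write_irt(model, file.path(config$out_dir, "irt_model.json"))
    list(model = coef(model))
  })

  run_stage("evaluate", function() {
    ac <- need("evaluate", "analysis_cohort")
    old_cl <- classify_risk(ac$q, config$risk_threshold)
    new_cl <- classify_risk(ac$irt_risk, config$risk_threshold)
    y <- ac$case_10yr
    nri_cat <- categorical_nri(old_cl, new_cl, y)
    nri_con <- continuous_nri(ac$q, ac$irt_risk, y)
    ci <- bootstrap_ci(function(i) {
      categorical_nri(old_cl[i], new_cl[i], y[i])$nri
    }, n = nrow(ac), B = config$B, seed = config$seed + 30L)
    c_old <- c_index(ac$q, ac$time, ac$event)
    c_new <- c_index(ac$irt_risk, ac$time, ac$event)
    sub <- subgroup_report(ac, function(sel) {
      categorical_nri(old_cl[sel], new_cl[sel], y[sel])
    }, age_cut = config$age_cut)
    sweep_tab <- age_threshold_sweep(ac, old_cl, new_cl, y,
                                     cuts = seq(30, 60, by = 5))
    write_result_table(sub, file.path(config$out_dir, "nri_subgroups.csv"),
                       config$seed, cfg_md5)
    write_result_table(sweep_tab,
                       file.path(config$out_dir, "nri_age_sweep.csv"),
                       config$seed, cfg_md5)
    list(nri_categorical = nri_cat$nri, nri_ci = c(ci$lo, ci$hi),
         nri_continuous = nri_con$nri, c_index_clinical = c_old$c_index,
         c_index_irt = c_new$c_index, subgroups = sub)
  })

  run_stage("gdm", function() {
    ac <- need("gdm", "analysis_cohort")
    g <- ac[ac$gdm == 1, , drop = FALSE]
    if (nrow(g) < 10 || length(unique(g$case_10yr)) < 2) {
      return(list(skipped = TRUE,
                  reason = "too few GDM women with both outcomes"))
    }
    cmp <- compare_groups(g$prs[g$case_10yr == 1], g$prs[g$case_10yr == 0])
    pool <- ac[ac$gdm == 0 & ac$female == 1, , drop = FALSE]
    ms <- match_controls(g, pool, ratio = 1, seed = config$seed + 40L)
    hz <- prs_hazard(g, adjustment = "q")
    write_result_table(as.data.frame(ms),
                       file.path(config$out_dir, "gdm_matches.csv"),
                       config$seed, cfg_md5)
    list(n_gdm = nrow(g), mean_prs_progressors = cmp$mean_a,
         mean_prs_nonprogressors = cmp$mean_b, p_compare = cmp$p,
         hr_per_sd = hz$hr_per_sd, hr_ci = hz$ci)
  })

  run_stage("cluster", function() {
    ccfg <- sim_config(seed = config$seed + 50L,
                       n_individuals = config$n_individuals)
    cc <- generate_cluster_cohort(ccfg)
    Xvars <- c("age", "bmi", "hba1c", "tg", "prs")
    sel <- select_k(cc[, Xvars], k_range = config$k_range,
                    n_init = config$n_init, seed = config$seed + 51L)
    fit <- sel$fits[["5"]]
    if (is.null(fit)) fit <- fit_mixture(cc[, Xvars], 5,
                                         n_init = config$n_init,
                                         seed = config$seed + 51L)
    lab <- label_clusters(fit, "integrated")
    ari <- adjusted_rand_index(lab$assignments, cc$true_cluster)
    an <- prs_anova(lab$assignments, cc$prs)
    haz <- complication_hazards(lab$assignments, cc$macro_time,
                                cc$macro_event, age = cc$age)
    out_tab <- data.frame(id = cc$id, cluster = lab$assignments,
                          true_cluster = cc$true_cluster)
    write_result_table(out_tab,
                       file.path(config$out_dir, "cluster_assignments.csv"),
                       config$seed, cfg_md5)
    write_result_table(sel$criteria,
                       file.path(config$out_dir, "cluster_criteria.csv"),
                       config$seed, cfg_md5)
    list(selected_k = sel$k, ari = ari, labels = lab$labels,
         anova_p = an$p, macro_hazards = haz$hr)
  })

  jsonlite::write_json(
    res, file.path(config$out_dir, "results.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE, na = "null")
  invisible(res)
}
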