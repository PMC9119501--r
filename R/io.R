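# File formats. Coordinates are 1-based (VCF convention); alleles uppercase.
# Tables written by the pipeline carry '# seed=... config_md5=...' header
# comments; all readers skip '#' lines.

sumstat_cols <- c("CHR", "POS", "SNP", "EA", "OA", "EAF", "BETA", "SE", "P")

#' Read and write GWAS summary statistics (TSV)
#'
#' Tab-delimited with columns CHR, POS, SNP, EA, OA, EAF, BETA, SE, P.
#' Malformed data lines (wrong field count or non-numeric statistics) are
#' counted and dropped; more than 10% malformed is a hard error.
#'
#' @param path file path.
#' @param x summary-statistic data frame.
#' @return `read_summary_stats` returns the data frame (with attribute
#'   `n_malformed`); `write_summary_stats` returns `path` invisibly.
#' @export
read_summary_stats <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) <= 1) {
    warning("empty summary-statistic file: ", path)
    out <- as.data.frame(setNames(rep(list(character(0)), 9), sumstat_cols))
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(sumstat_cols, header)
  if (length(miss) > 0) {
    stop("summary-statistic file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ok_len <- lengths(body) == length(header)
  rows <- do.call(rbind, body[ok_len])
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- header
  df <- df[, sumstat_cols]
  for (col in c("POS", "EAF", "BETA", "SE", "P")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  bad <- !stats::complete.cases(df[, c("POS", "EAF", "BETA", "SE", "P")])
  n_malformed <- sum(!ok_len) + sum(bad)
  if (n_malformed > 0.10 * (length(lines) - 1)) {
    stop(sprintf("%d of %d data lines malformed in %s", n_malformed,
                 length(lines) - 1, path), call. = FALSE)
  }
  df <- df[!bad, , drop = FALSE]
  df$EA <- toupper(df$EA)
  df$OA <- toupper(df$OA)
  rownames(df) <- NULL
  attr(df, "n_malformed") <- n_malformed
  df
}

#' @rdname read_summary_stats
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(all(sumstat_cols %in% names(x)))
  utils::write.table(x[, sumstat_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write scoring files (PGS Catalog dialect)
#'
#' Tab-delimited with columns rsID, chr_name, chr_position, effect_allele,
#' other_allele, effect_weight.
#'
#' @param path file path.
#' @param score a [score_file()].
#' @return `read_score_file` returns a [score_file()]; `write_score_file`
#'   returns `path` invisibly.
#' @export
read_score_file <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("rsID", "chr_name", "chr_position", "effect_allele",
            "other_allele", "effect_weight")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("score file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  score_file(df$rsID, df$chr_name, df$chr_position, df$effect_allele,
             df$other_allele, df$effect_weight)
}

#' @rdname read_score_file
#' @export
write_score_file <- function(score, path) {
  utils::write.table(as.data.frame(score), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

cohort_mandatory <- c("id", "age", "female")

#' Read and write cohort tables (CSV)
#'
#' The cohort schema is one row per individual with mandatory columns `id`,
#' `age`, `female` and any additional covariate, score, follow-up, or event
#' columns. Rows failing validation (negative or non-numeric age, `female`
#' outside 0/1) are rejected and listed in the attached report.
#'
#' @param path file path.
#' @param cohort cohort data frame.
#' @return `read_cohort` returns the validated data frame with attribute
#'   `validation` (data frame of rejected rows and reasons);
#'   `write_cohort` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(cohort_mandatory, names(df))
  if (length(miss) > 0) {
    stop("cohort file missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$age <- suppressWarnings(as.numeric(df$age))
  reasons <- character(0)
  bad_rows <- integer(0)
  bad_age <- which(is.na(df$age) | df$age < 0)
  if (length(bad_age) > 0) {
    bad_rows <- c(bad_rows, bad_age)
    reasons <- c(reasons, rep("invalid age", length(bad_age)))
  }
  bad_sex <- which(!df$female %in% c(0, 1))
  if (length(bad_sex) > 0) {
    bad_rows <- c(bad_rows, bad_sex)
    reasons <- c(reasons, rep("female must be 0/1", length(bad_sex)))
  }
  report <- data.frame(row = bad_rows, reason = reasons)
  out <- if (length(bad_rows) > 0) df[-unique(bad_rows), , drop = FALSE]
         else df
  rownames(out) <- NULL
  attr(out, "validation") <- report
  out
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genotype dosages as a minimal VCF with a DS FORMAT field
#'
#' @param dosages individuals x variants matrix (column names = variant ids,
#'   row names = sample ids).
#' @param variants variant metadata (`id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`). The effect allele is written as ALT so that DS counts
#'   effect-allele copies.
#' @param path output path (plain-text .vcf).
#' @return `path`, invisibly.
#' @export
write_vcf_dosage <- function(dosages, variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">"),
             con)
  samples <- rownames(dosages)
  if (is.null(samples)) samples <- sprintf("s%04d", seq_len(nrow(dosages)))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  for (j in seq_len(nrow(variants))) {
    ds <- format(round(dosages[, variants$id[j]], 4), trim = TRUE)
    writeLines(paste(c(variants$chrom[j], variants$pos[j], variants$id[j],
                       variants$other_allele[j], variants$effect_allele[j],
                       ".", "PASS", ".", "DS", ds), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Uses the DS FORMAT field when present, falling back to GT allele counts.
#' Dosages count ALT (effect-allele) copies.
#'
#' @param path VCF path (plain text).
#' @return list with `dosages` (individuals x variants) and `variants`
#'   metadata, mirroring [generate_genotypes()].
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  has_ds <- any(grepl("DS", v@gt[, "FORMAT"]))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
  }
  dos <- t(ds)
  colnames(dos) <- fix$ID
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         effect_allele = toupper(fix$ALT),
                         other_allele = toupper(fix$REF),
                         eaf = colMeans(dos, na.rm = TRUE) / 2,
                         stringsAsFactors = FALSE)
  list(dosages = dos, variants = variants)
}

#' Read and write a plain dosage matrix (TSV)
#'
#' First column `id`, one column per variant.
#'
#' @param dosages matrix; `path` file path.
#' @return `read_dosage_tsv` returns the matrix; the writer returns `path`
#'   invisibly.
#' @export
write_dosage_tsv <- function(dosages, path) {
  df <- data.frame(id = rownames(dosages), dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
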