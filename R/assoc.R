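# eQTL-wide association study: phenotype QC, variant filtering, age- and
# sex-adjusted per-variant OLS, multiple-testing gating, summary-stats I/O.

summary_stat_columns <- c("variant_id", "chrom", "pos", "effect_allele",
                          "other_allele", "eaf", "beta", "se", "p", "n",
                          "trait", "info")

#' Quality-control configuration
#'
#' @param sd_limit phenotype outlier cut in standard deviations (default 4:
#'   values beyond mean +/- 4 SD are set missing).
#' @param info_min minimum imputation quality score (default 0.8, inclusive).
#' @param maf_min minimum minor allele frequency (default 0.01, strict).
#' @param log_flags named logical vector: traits to log-transform before the
#'   outlier scan.
#' @return an object of class \code{qc_config}.
#' @export
qc_config <- function(sd_limit = 4, info_min = 0.8, maf_min = 0.01,
                      log_flags = NULL) {
  if (sd_limit <= 0) stop("sd_limit must be positive")
  if (info_min < 0 || info_min > 1 || maf_min < 0 || maf_min > 1)
    stop("info_min and maf_min must lie in [0, 1]")
  structure(list(sd_limit = sd_limit, info_min = info_min,
                 maf_min = maf_min, log_flags = log_flags),
            class = "qc_config")
}

#' Remove phenotype outliers
#'
#' Values beyond \code{mean +/- sd_limit * SD} are set missing. Mean and SD
#' are computed once on the full non-missing sample (single pass, so the
#' operation is idempotent); when the trait is flagged for log transformation
#' the scan runs on the log scale and the returned values are log-transformed.
#' A constant vector (SD = 0) is returned unchanged.
#'
#' @param values numeric phenotype vector (may contain \code{NA}).
#' @param config a [qc_config()].
#' @param trait trait name, used to look up \code{log_flags}.
#' @return list with \code{values} (cleaned vector, same length),
#'   \code{removed} (integer indices set missing) and \code{report}
#'   (one-row data frame: n, n_removed, mean, sd, log_applied).
#' @export
clean_phenotypes <- function(values, config = qc_config(), trait = "trait") {
  ok <- !is.na(values)
  if (sum(ok) < 10) stop("need >= 10 non-missing values for outlier QC")
  log_applied <- isTRUE(config$log_flags[[trait]])
  x <- values
  if (log_applied) {
    if (any(x[ok] <= 0)) stop("log transform requested for non-positive trait")
    x <- log(x)
  }
  mu <- mean(x[ok])
  sdev <- stats::sd(x[ok])
  removed <- integer(0)
  if (sdev > 0) {
    removed <- which(ok & abs(x - mu) > config$sd_limit * sdev)
    x[removed] <- NA_real_
  }
  list(values = x,
       removed = removed,
       report = data.frame(trait = trait, n = sum(ok),
                           n_removed = length(removed), mean = mu, sd = sdev,
                           log_applied = log_applied))
}

#' Filter variants on imputation quality and MAF
#'
#' Keeps records with imputation \code{info >= info_min} and minor allele
#' frequency strictly above \code{maf_min} (MAF computed as
#' \code{min(eaf, 1 - eaf)}). A missing info score passes the filter but is
#' counted; malformed rows (missing or out-of-range eaf) are dropped with a
#' warning and counted.
#'
#' @param records summary-statistics data frame (see [read_summary_stats()]).
#' @param config a [qc_config()].
#' @return list with \code{records} (retained rows) and \code{counts}
#'   (named integer vector: input, kept, fail_info, fail_maf, missing_info,
#'   malformed).
#' @export
filter_variants <- function(records, config = qc_config()) {
  n_in <- nrow(records)
  malformed <- is.na(records$eaf) | records$eaf <= 0 | records$eaf >= 1
  if (any(malformed))
    warning(sprintf("%d malformed record(s) skipped", sum(malformed)))
  rec <- records[!malformed, , drop = FALSE]
  info <- if ("info" %in% names(rec)) rec$info else rep(NA_real_, nrow(rec))
  missing_info <- is.na(info)
  pass_info <- missing_info | info >= config$info_min
  maf <- pmin(rec$eaf, 1 - rec$eaf)
  pass_maf <- maf - config$maf_min > 1e-12  # strict ">", fp-safe at bound
  keep <- pass_info & pass_maf
  list(records = rec[keep, , drop = FALSE],
       counts = c(input = n_in, kept = sum(keep),
                  fail_info = sum(!pass_info),
                  fail_maf = sum(pass_info & !pass_maf),
                  missing_info = sum(missing_info & keep),
                  malformed = sum(malformed)))
}

#' Age- and sex-adjusted per-variant association scan
#'
#' For each variant, ordinary least squares of the phenotype on additive
#' dosage with age and sex as covariates. Beta, SE and the two-sided p-value
#' come from the coefficient t statistic with residual degrees of freedom.
#' Rows with missing phenotype or dosage are dropped listwise per variant;
#' rank-deficient designs (e.g. monomorphic variants) yield a record with
#' missing beta/SE and a reason in the \code{note} column.
#'
#' Complete-data designs share one covariate projection
#' (Frisch-Waugh-Lovell), so genome-scale scans cost one matrix product
#' rather than one \code{lm} per variant; the estimates are identical to the
#' full regression.
#'
#' @param dosages n x m dosage matrix (columns = variants).
#' @param phenotype numeric vector, length n.
#' @param covariates data frame or matrix with columns \code{age} and
#'   \code{sex} (additional columns are adjusted for too).
#' @param variant_meta data frame with columns \code{variant_id, chrom, pos,
#'   effect_allele, other_allele} (and optionally \code{maf}); defaults to
#'   the dosage column names.
#' @param trait trait label stamped on the output records.
#' @return a summary-statistics data frame (one row per variant) with the
#'   standard columns plus \code{note}.
#' @export
run_eqtlwas <- function(dosages, phenotype, covariates,
                        variant_meta = NULL, trait = "trait") {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (length(phenotype) != n) stop("phenotype length must match dosage rows")
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) stop("covariate rows must match dosage rows")
  if (is.null(variant_meta)) {
    ids <- colnames(dosages) %||% sprintf("snp_%02d", seq_len(m))
    variant_meta <- data.frame(variant_id = ids, chrom = NA_character_,
                               pos = NA_integer_, effect_allele = NA_character_,
                               other_allele = NA_character_,
                               stringsAsFactors = FALSE)
  }
  ok_pheno <- stats::complete.cases(phenotype, covariates)
  if (sum(ok_pheno) < ncol(covariates) + 3)
    stop("too few complete phenotype/covariate rows")
  if (stats::sd(phenotype[ok_pheno]) == 0)
    stop("phenotype is constant after QC")

  X <- cbind(1, as.matrix(covariates))
  out <- data.frame(variant_id = variant_meta$variant_id,
                    chrom = variant_meta$chrom, pos = variant_meta$pos,
                    effect_allele = variant_meta$effect_allele,
                    other_allele = variant_meta$other_allele,
                    eaf = NA_real_, beta = NA_real_, se = NA_real_,
                    p = NA_real_, n = NA_integer_, trait = trait,
                    info = NA_real_, note = NA_character_,
                    stringsAsFactors = FALSE)

  complete_dos <- !anyNA(dosages)
  if (complete_dos && all(ok_pheno)) {
    # shared covariate projection: residualize y and every dosage column once
    qr_x <- qr(X)
    y_res <- qr.resid(qr_x, phenotype)
    g_res <- qr.resid(qr_x, dosages)
    gss <- colSums(g_res^2)
    df <- n - ncol(X) - 1L
    mono <- gss < 1e-12
    beta <- ifelse(mono, NA_real_, colSums(g_res * y_res) / gss)
    rss <- sum(y_res^2) - ifelse(mono, 0, beta^2 * gss)
    sigma2 <- rss / df
    se <- sqrt(sigma2 / gss)
    se[mono] <- NA_real_
    tstat <- beta / se
    out$eaf <- colMeans(dosages) / 2
    out$beta <- beta
    out$se <- se
    out$p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    out$n <- n
    out$note[mono] <- "monomorphic or rank-deficient"
  } else {
    for (j in seq_len(m)) {
      use <- ok_pheno & !is.na(dosages[, j])
      nj <- sum(use)
      out$n[j] <- nj
      if (nj < ncol(X) + 2) { out$note[j] <- "too few complete rows"; next }
      g <- dosages[use, j]
      out$eaf[j] <- mean(g) / 2
      if (stats::sd(g) == 0) {
        out$note[j] <- "monomorphic or rank-deficient"
        next
      }
      fit <- stats::lm.fit(cbind(X[use, , drop = FALSE], g), phenotype[use])
      cf <- fit$coefficients
      k <- length(cf)
      df <- nj - fit$rank
      rss <- sum(fit$residuals^2)
      R <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                              drop = FALSE])
      se <- sqrt(rss / df * R[k, k])
      out$beta[j] <- cf[k]
      out$se[j] <- se
      out$p[j] <- 2 * stats::pt(abs(cf[k] / se), df, lower.tail = FALSE)
    }
  }
  out
}

#' Bonferroni-corrected p-value threshold
#'
#' @param n_tests total number of tests scheduled (>= 1).
#' @param alpha family-wise error rate, default 0.05.
#' @return \code{alpha / n_tests}.
#' @examples
#' bonferroni_threshold(273742)  # 1.83e-7, printed as 1.8e-7
#' bonferroni_threshold(54)      # 9.26e-4, printed as 9.3e-4
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive count")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / n_tests
}

#' Count association signals and distinct lead SNPs
#'
#' @param records summary-statistics data frame.
#' @param threshold p-value threshold (strict \code{<}); \code{NULL} counts
#'   all rows (used with pre-filtered tables such as the bundled association
#'   fixture, where printed p-values are not re-thresholded).
#' @return list with \code{n_signals} and \code{n_unique_lead_snps}.
#' @export
count_signals <- function(records, threshold = NULL) {
  hits <- if (is.null(threshold)) records
          else records[!is.na(records$p) & records$p < threshold, ,
                       drop = FALSE]
  list(n_signals = nrow(hits),
       n_unique_lead_snps = length(unique(hits$variant_id)))
}

#' Collapse gated hits to one lead SNP per locus
#'
#' Greedy clumping: repeatedly take the remaining record with the smallest p
#' (ties broken by \code{variant_id}) as a lead SNP and drop everything
#' within \code{window} bp of it on the same chromosome.
#'
#' @param records summary-statistics data frame of gated hits.
#' @param window locus radius in bp (default 1 Mb).
#' @return the lead-SNP rows, ordered by p.
#' @export
lead_snps <- function(records, window = 1e6) {
  rec <- records[!is.na(records$p), , drop = FALSE]
  rec <- rec[order(rec$p, rec$variant_id), , drop = FALSE]
  leads <- rec[0, , drop = FALSE]
  while (nrow(rec) > 0) {
    lead <- rec[1, , drop = FALSE]
    leads <- rbind(leads, lead)
    same <- rec$chrom == lead$chrom & !is.na(rec$pos) & !is.na(lead$pos) &
      abs(rec$pos - lead$pos) <= window
    same[is.na(same)] <- FALSE
    rec <- rec[!(same | rec$variant_id == lead$variant_id), , drop = FALSE]
  }
  leads
}

#' Read / write summary statistics
#'
#' Tab-delimited text with the exact header \code{variant_id, chrom, pos,
#' effect_allele, other_allele, eaf, beta, se, p, n, trait, info}; positions
#' 1-based; missing values written as \code{NA}.
#'
#' @param path file path.
#' @param records summary-statistics data frame.
#' @return \code{read_summary_stats} returns the data frame;
#'   \code{write_summary_stats} returns the path invisibly.
#' @export
read_summary_stats <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  missing_cols <- setdiff(summary_stat_columns, names(rec))
  if (length(missing_cols) > 0)
    stop("missing summary-stat columns: ",
         paste(missing_cols, collapse = ", "))
  rec
}

#' @rdname read_summary_stats
#' @export
write_summary_stats <- function(records, path) {
  for (col in setdiff(summary_stat_columns, names(records)))
    records[[col]] <- NA
  records <- records[, c(summary_stat_columns,
                         setdiff(names(records), summary_stat_columns)),
                     drop = FALSE]
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Manhattan-plot input table
#'
#' @param records summary-statistics data frame.
#' @param threshold genome-wide p threshold used for the flag column.
#' @return data frame with \code{chrom, pos, neg_log10_p, trait,
#'   above_threshold}.
#' @export
manhattan_table <- function(records, threshold) {
  data.frame(chrom = records$chrom, pos = records$pos,
             neg_log10_p = -log10(records$p), trait = records$trait,
             above_threshold = !is.na(records$p) & records$p < threshold)
}
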