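# Two-sample Mendelian randomization with a single instrument per gene x
# tissue: cis instrument selection, exposure/outcome harmonization, Wald
# ratio, Steiger directionality test, proxy-SNP substitution.

#' Select cis instruments per gene and tissue
#'
#' Keeps eQTL records within the cis window of their gene's transcription
#' start site (inclusive at exactly the window edge) with p strictly below
#' the instrument threshold, then retains one lead instrument per gene x
#' tissue: smallest p, ties broken by \code{variant_id}.
#'
#' @param eqtl_records summary-statistics data frame with additional columns
#'   \code{gene} and \code{tissue}.
#' @param p_threshold instrument p-value threshold, strict \code{<}
#'   (default 1e-4).
#' @param cis_window cis-window half-width around the TSS (default 1 Mb).
#' @param tss named vector or data frame (\code{gene}, \code{tss}) of
#'   transcription start sites.
#' @return data frame of lead instruments, one row per gene x tissue that
#'   has any passing record; gene x tissue combinations with none are
#'   absent (callers treat absence as "no instrument", not an error).
#' @export
select_instruments <- function(eqtl_records, p_threshold = 1e-4,
                               cis_window = 1e6, tss) {
  if (is.data.frame(tss)) tss <- stats::setNames(tss$tss, tss$gene)
  rec <- eqtl_records
  rec$tss <- unname(tss[rec$gene])
  keep <- !is.na(rec$tss) & !is.na(rec$p) &
    abs(rec$pos - rec$tss) <= cis_window & rec$p < p_threshold
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0L) return(rec)
  rec <- rec[order(rec$gene, rec$tissue, rec$p, rec$variant_id), ,
             drop = FALSE]
  lead <- !duplicated(rec[, c("gene", "tissue")])
  out <- rec[lead, , drop = FALSE]
  rownames(out) <- NULL
  out
}

complement_alleles <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(a1, a2) {
  a1 == complement_alleles(a2)
}

#' Harmonize exposure and outcome summary statistics for one variant
#'
#' Aligns the outcome record to the exposure's effect allele. If the outcome
#' effect allele equals the exposure's other allele, the outcome beta sign
#' and EAF are flipped. When alleles do not match directly, strand-flipped
#' (complementary) alleles are tried before failing. Palindromic pairs
#' (A/T, C/G) are resolved by allele frequency when both minor allele
#' frequencies are below \code{palindromic_eaf_max}; otherwise the pair is
#' dropped (status \code{"dropped"}).
#'
#' @param exposure,outcome one-row summary-statistics data frames for the
#'   same variant (or proxy-mapped onto it).
#' @param palindromic_eaf_max frequency cutoff below which a palindromic
#'   pair is considered resolvable (default 0.42).
#' @return an object of class \code{harmonized_pair}: list with
#'   \code{variant_id}, aligned \code{exposure} and \code{outcome} records,
#'   \code{aligned_effect_allele}, \code{flips_applied} and
#'   \code{palindromic_status} (\code{"not"}, \code{"resolved"} or
#'   \code{"dropped"}). Irreconcilable allele sets raise an error.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_max = 0.42) {
  stopifnot(nrow(exposure) == 1L, nrow(outcome) == 1L)
  if (is.na(exposure$se) || is.na(outcome$se) ||
      exposure$se <= 0 || outcome$se <= 0)
    stop("both records need positive standard errors")
  e1 <- toupper(exposure$effect_allele); e2 <- toupper(exposure$other_allele)
  o1 <- toupper(outcome$effect_allele); o2 <- toupper(outcome$other_allele)
  pal <- is_palindromic(e1, e2)

  flip_outcome <- function(out) {
    out$beta <- -out$beta
    out$eaf <- 1 - out$eaf
    tmp <- out$effect_allele
    out$effect_allele <- out$other_allele
    out$other_allele <- tmp
    out
  }

  status <- "not"
  flipped <- FALSE
  if (pal) {
    if (!setequal(c(o1, o2), c(e1, e2)))
      stop("cannot harmonize: allele sets differ (", e1, "/", e2, " vs ",
           o1, "/", o2, ")")
    maf_e <- min(exposure$eaf, 1 - exposure$eaf)
    maf_o <- min(outcome$eaf, 1 - outcome$eaf)
    if (is.na(maf_e) || is.na(maf_o) ||
        maf_e >= palindromic_eaf_max || maf_o >= palindromic_eaf_max) {
      status <- "dropped"
    } else {
      status <- "resolved"
      # allele labels are strand-ambiguous for palindromic pairs; the
      # frequency side (minor vs major) is the only alignment signal
      exp_minor_is_effect <- exposure$eaf < 0.5
      out_minor_is_effect <- outcome$eaf < 0.5
      if (exp_minor_is_effect != out_minor_is_effect) {
        outcome <- flip_outcome(outcome)
        flipped <- TRUE
      }
      outcome$effect_allele <- e1
      outcome$other_allele <- e2
    }
  } else if (o1 == e1 && o2 == e2) {
    # already aligned
  } else if (o1 == e2 && o2 == e1) {
    outcome <- flip_outcome(outcome)
    flipped <- TRUE
  } else if (complement_alleles(o1) == e1 && complement_alleles(o2) == e2) {
    outcome$effect_allele <- e1
    outcome$other_allele <- e2
  } else if (complement_alleles(o1) == e2 && complement_alleles(o2) == e1) {
    outcome$effect_allele <- e2
    outcome$other_allele <- e1
    outcome <- flip_outcome(outcome)
    flipped <- TRUE
  } else {
    stop("cannot harmonize: allele sets differ (", e1, "/", e2, " vs ",
         o1, "/", o2, ")")
  }

  structure(list(variant_id = exposure$variant_id,
                 exposure = exposure, outcome = outcome,
                 aligned_effect_allele = e1,
                 flips_applied = flipped,
                 palindromic_status = status),
            class = "harmonized_pair")
}

#' Wald ratio MR estimate
#'
#' Single-instrument causal-effect estimate: outcome effect divided by
#' exposure effect. The default standard error is the first-order delta
#' method \code{|se_out / beta_exp|}, the convention for single-SNP Wald
#' MR; \code{second_order = TRUE} adds the exposure-uncertainty term
#' \code{beta_out^2 * se_exp^2 / beta_exp^4}. The two-sided p-value is
#' computed against the standard normal (two-sample summary setting).
#'
#' @param pair a [harmonize()] result (must not have palindromic status
#'   \code{"dropped"}).
#' @param second_order include the exposure-uncertainty variance term?
#' @param exposure_name,outcome_name labels carried into the result.
#' @return an object of class \code{wald_result}: list with \code{beta_mr},
#'   \code{se_mr}, \code{p}, \code{exposure_name}, \code{outcome_name},
#'   \code{variant_id}.
#' @export
wald_ratio <- function(pair, second_order = FALSE,
                       exposure_name = pair$exposure$trait,
                       outcome_name = pair$outcome$trait) {
  stopifnot(inherits(pair, "harmonized_pair"))
  if (pair$palindromic_status == "dropped")
    stop("pair was dropped during harmonization (ambiguous palindromic ",
         "alleles)")
  b_exp <- pair$exposure$beta
  if (is.na(b_exp) || b_exp == 0)
    stop("Wald ratio undefined: exposure beta is zero or missing")
  b_out <- pair$outcome$beta
  beta_mr <- b_out / b_exp
  var_mr <- (pair$outcome$se / b_exp)^2
  if (second_order)
    var_mr <- var_mr + b_out^2 * pair$exposure$se^2 / b_exp^4
  se_mr <- sqrt(var_mr)
  p <- 2 * stats::pnorm(abs(beta_mr / se_mr), lower.tail = FALSE)
  structure(list(beta_mr = beta_mr, se_mr = se_mr, p = p,
                 exposure_name = exposure_name, outcome_name = outcome_name,
                 variant_id = pair$variant_id),
            class = "wald_result")
}

# Correlation implied by a regression t statistic: r = t / sqrt(t^2 + df).
t_to_r <- function(beta, se, n, n_covariates = 0) {
  df <- n - 2 - n_covariates
  if (df <= 1) stop("sample too small to recover a correlation")
  t <- beta / se
  t / sqrt(t^2 + df)
}

#' Steiger directionality test
#'
#' Tests whether the instrument explains more variance in the exposure than
#' in the outcome (the expected pattern when exposure causes outcome). Each
#' study's SNP-trait correlation is reconstructed from the coefficient's t
#' statistic (\code{r = t / sqrt(t^2 + df)}); the two-independent-samples
#' Fisher z statistic is
#' \deqn{z = (atanh|r_{exp}| - atanh|r_{out}|) /
#'       \sqrt{1/(n_{exp}-3) + 1/(n_{out}-3)}}
#' with a two-sided p-value. The null hypothesis is equal SNP-exposure and
#' SNP-outcome correlations.
#'
#' @param pair a [harmonize()] result.
#' @param n_exp,n_out per-study sample sizes (> 3); default to the records'
#'   \code{n} columns.
#' @return an object of class \code{steiger_result}: list with
#'   \code{r2_exposure}, \code{r2_outcome}, \code{z_statistic}, \code{p} and
#'   \code{direction_ok} (\code{TRUE} when |r_exp| > |r_out|).
#' @export
steiger_test <- function(pair, n_exp = pair$exposure$n,
                         n_out = pair$outcome$n) {
  stopifnot(inherits(pair, "harmonized_pair"))
  if (is.na(n_exp) || is.na(n_out) || n_exp <= 3 || n_out <= 3)
    stop("both sample sizes must exceed 3")
  if (is.na(pair$exposure$se) || is.na(pair$outcome$se))
    stop("cannot reconstruct t statistics: missing standard error")
  r_exp <- abs(t_to_r(pair$exposure$beta, pair$exposure$se, n_exp))
  r_out <- abs(t_to_r(pair$outcome$beta, pair$outcome$se, n_out))
  z <- (atanh(r_exp) - atanh(r_out)) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  structure(list(r2_exposure = r_exp^2, r2_outcome = r_out^2,
                 z_statistic = z, p = p,
                 direction_ok = r_exp > r_out),
            class = "steiger_result")
}

#' Find a proxy SNP in LD with a missing target
#'
#' Returns the candidate with the largest r-squared to the target among
#' those present in the outcome dataset and reaching \code{r2_min}; ties are
#' broken by \code{variant_id}.
#'
#' @param target variant id absent from the outcome dataset.
#' @param ld either a dosage matrix (columns named by variant) or a
#'   correlation matrix with dimnames; must cover the target.
#' @param available character vector of variant ids present in the outcome
#'   dataset.
#' @param r2_min minimum r-squared (default 0.8, inclusive).
#' @return list with \code{proxy} (variant id or \code{NA}) and \code{r2}.
#' @export
find_proxy <- function(target, ld, available, r2_min = 0.8) {
  R <- if (is.matrix(ld) && !is.null(rownames(ld)) &&
           identical(rownames(ld), colnames(ld)) && nrow(ld) == ncol(ld) &&
           all(abs(diag(ld) - 1) < 1e-6)) ld else ld_matrix(ld)
  if (!target %in% rownames(R))
    stop("target variant ", target, " absent from the LD source")
  cand <- setdiff(intersect(available, rownames(R)), target)
  if (length(cand) == 0L) return(list(proxy = NA_character_, r2 = NA_real_))
  r2 <- R[target, cand]^2
  ord <- order(-r2, cand)
  best <- ord[1]
  if (r2[best] < r2_min) return(list(proxy = NA_character_, r2 = NA_real_))
  list(proxy = cand[best], r2 = unname(r2[best]))
}

#' Run single-instrument MR for a table of exposure/outcome pairs
#'
#' Convenience wrapper: harmonizes each instrument against the outcome
#' records, computes the Wald ratio and Steiger test, and collects the
#' standard MR results table. Pairs that cannot be harmonized (irreconcilable
#' or ambiguous-palindromic alleles) are reported with missing estimates and
#' a reason, mirroring exclusions such as genes whose instrument cannot be
#' aligned across datasets.
#'
#' @param instruments data frame of exposure records (columns \code{gene},
#'   \code{tissue} plus the summary-stat columns).
#' @param outcome_records outcome summary statistics (one trait).
#' @param proxy_ld optional LD source for proxy substitution when an
#'   instrument is absent from the outcome records.
#' @param r2_min proxy threshold (default 0.8).
#' @return data frame: exposure, tissue, outcome, variant_id, beta_mr,
#'   se_mr, p, steiger_p, direction_ok, proxy_used, note.
#' @export
mr_run <- function(instruments, outcome_records, proxy_ld = NULL,
                   r2_min = 0.8) {
  rows <- lapply(seq_len(nrow(instruments)), function(i) {
    inst <- instruments[i, , drop = FALSE]
    out_row <- data.frame(
      exposure = inst$gene %||% inst$trait, tissue = inst$tissue %||% NA,
      outcome = outcome_records$trait[1], variant_id = inst$variant_id,
      beta_mr = NA_real_, se_mr = NA_real_, p = NA_real_,
      steiger_p = NA_real_, direction_ok = NA, proxy_used = NA_character_,
      note = NA_character_, stringsAsFactors = FALSE)
    hit <- outcome_records[outcome_records$variant_id == inst$variant_id, ,
                           drop = FALSE]
    if (nrow(hit) == 0L && !is.null(proxy_ld)) {
      px <- find_proxy(inst$variant_id, proxy_ld,
                       outcome_records$variant_id, r2_min)
      if (!is.na(px$proxy)) {
        hit <- outcome_records[outcome_records$variant_id == px$proxy, ,
                               drop = FALSE]
        out_row$proxy_used <- px$proxy
      }
    }
    if (nrow(hit) == 0L) {
      out_row$note <- "instrument absent from outcome (no proxy)"
      return(out_row)
    }
    res <- tryCatch({
      pair <- harmonize(inst[, summary_stat_columns
                             [summary_stat_columns %in% names(inst)],
                             drop = FALSE],
                        hit[1, , drop = FALSE])
      if (pair$palindromic_status == "dropped") {
        out_row$note <- "dropped: ambiguous palindromic alleles"
        out_row
      } else {
        w <- wald_ratio(pair)
        s <- steiger_test(pair)
        out_row$beta_mr <- w$beta_mr
        out_row$se_mr <- w$se_mr
        out_row$p <- w$p
        out_row$steiger_p <- s$p
        out_row$direction_ok <- s$direction_ok
        out_row
      }
    }, error = function(e) {
      out_row$note <- conditionMessage(e)
      out_row
    })
    res
  })
  do.call(rbind, rows)
}

#' Volcano-plot input table for MR results
#'
#' @param mr_results a [mr_run()] table.
#' @return data frame with \code{exposure, tissue, outcome, beta_mr,
#'   neg_log10_p}.
#' @export
mr_volcano_table <- function(mr_results) {
  data.frame(exposure = mr_results$exposure, tissue = mr_results$tissue,
             outcome = mr_results$outcome, beta_mr = mr_results$beta_mr,
             neg_log10_p = -log10(mr_results$p))
}
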