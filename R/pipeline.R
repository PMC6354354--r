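# Pipeline orchestration: discovery workflow (eQTLWAS -> fine-mapping ->
# tissue-specific MR -> multiple-trait colocalization) and the genome-wide
# scan mode, with configuration, branch-level failure isolation, logging
# and reporting.

#' Pipeline configuration
#'
#' All stage thresholds in one validated object. Defaults are the study
#' conditions of the analysis this package implements: family-wise alpha
#' 0.05 with Bonferroni correction at the scheduled test count, instrument
#' p < 1e-4, 1-Mb windows, colocalization over >= 50 common SNPs at
#' MAF >= 0.05 with priors (1e-4, 1e-6, 1e-7) and a 0.8 summed-PPA decision
#' rule, proxy substitution at r^2 >= 0.8, imputation info >= 0.8,
#' association MAF > 0.01, phenotype outliers at 4 SD, and at most five
#' causal variants per fine-mapped region.
#'
#' @param alpha family-wise error rate.
#' @param instrument_p cis-instrument p threshold (strict).
#' @param ppa_threshold summed-PPA decision threshold.
#' @param r2_proxy minimum proxy r-squared.
#' @param window cis/region half-width in bp.
#' @param min_snps minimum common SNPs for colocalization.
#' @param maf_moloc colocalization MAF filter (inclusive).
#' @param info_min imputation-quality filter (inclusive).
#' @param maf_assoc association MAF filter (strict).
#' @param sd_limit phenotype outlier cut in SDs.
#' @param k_max fine-mapping causal-variant cap.
#' @param priors colocalization per-SNP priors (single, double, triple).
#' @param finemap_prior_sd fine-mapping effect prior SD.
#' @param moloc_prior_sd Wakefield effect prior SD.
#' @param tissues tissue labels analysed.
#' @param traits trait labels analysed.
#' @param seed master seed for every stochastic stage.
#' @param stages character vector of enabled stages, any of
#'   \code{c("assoc", "finemap", "mr", "moloc")}.
#' @param paths optional named list of file paths for file-based runs.
#' @return an object of class \code{pipeline_config} with a provenance
#'   \code{fingerprint}.
#' @export
pipeline_config <- function(alpha = 0.05, instrument_p = 1e-4,
                            ppa_threshold = 0.8, r2_proxy = 0.8,
                            window = 1e6, min_snps = 50, maf_moloc = 0.05,
                            info_min = 0.8, maf_assoc = 0.01, sd_limit = 4,
                            k_max = 5, priors = c(1e-4, 1e-6, 1e-7),
                            finemap_prior_sd = 0.05, moloc_prior_sd = 0.15,
                            tissues = "whole_blood", traits = "trait",
                            seed = 1L,
                            stages = c("assoc", "finemap", "mr", "moloc"),
                            paths = list()) {
  stopifnot(alpha > 0, alpha < 1, instrument_p > 0, instrument_p < 1,
            ppa_threshold > 0, ppa_threshold <= 1,
            r2_proxy >= 0, r2_proxy <= 1, window > 0, min_snps >= 1,
            maf_moloc >= 0, maf_moloc <= 0.5, info_min >= 0, info_min <= 1,
            maf_assoc >= 0, maf_assoc <= 0.5, sd_limit > 0, k_max >= 1,
            length(priors) == 3, all(priors > 0), all(priors < 1),
            length(tissues) >= 1, length(traits) >= 1)
  cfg <- structure(list(alpha = alpha, instrument_p = instrument_p,
                        ppa_threshold = ppa_threshold, r2_proxy = r2_proxy,
                        window = window, min_snps = min_snps,
                        maf_moloc = maf_moloc, info_min = info_min,
                        maf_assoc = maf_assoc, sd_limit = sd_limit,
                        k_max = k_max, priors = priors,
                        finemap_prior_sd = finemap_prior_sd,
                        moloc_prior_sd = moloc_prior_sd,
                        tissues = tissues, traits = traits,
                        seed = as.integer(seed), stages = stages,
                        paths = paths),
                   class = "pipeline_config")
  cfg$fingerprint <- object_fingerprint(unclass(cfg))
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' Field names in the file mirror [pipeline_config()] arguments exactly.
#'
#' @param config a \code{pipeline_config}.
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$fingerprint <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Per-tissue eQTL / mQTL / trait summary statistics from a cohort
#'
#' Runs the age- and sex-adjusted association scan of every variant against
#' each molecular or complex phenotype of a synthetic cohort, producing the
#' summary-statistics tables the two-sample stages consume.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param what \code{"eqtl"} (per gene and tissue), \code{"mqtl"} (per CpG)
#'   or \code{"gwas"} (per complex trait).
#' @return a summary-statistics data frame with extra columns \code{gene} +
#'   \code{tissue} (eqtl), \code{cpg} (mqtl), or none (gwas).
#' @export
cohort_summary_stats <- function(cohort, what = c("eqtl", "mqtl", "gwas")) {
  what <- match.arg(what)
  covars <- data.frame(age = cohort$age, sex = cohort$sex)
  scan <- function(y, label) {
    run_eqtlwas(cohort$dosages, y, covars, cohort$variant_meta,
                trait = label)
  }
  if (what == "eqtl") {
    out <- list()
    for (tis in names(cohort$tissue_expression)) {
      em <- cohort$tissue_expression[[tis]]
      for (g in colnames(em)) {
        rec <- scan(em[, g], g)
        rec$gene <- g
        rec$tissue <- tis
        out[[length(out) + 1L]] <- rec
      }
    }
    do.call(rbind, out)
  } else if (what == "mqtl") {
    out <- lapply(colnames(cohort$methylation), function(cpg) {
      rec <- scan(cohort$methylation[, cpg], cpg)
      rec$cpg <- cpg
      rec
    })
    do.call(rbind, out)
  } else {
    out <- lapply(names(cohort$traits), function(tr)
      scan(cohort$traits[[tr]], tr))
    do.call(rbind, out)
  }
}

log_entry <- function(stage, locus, action, reason = "") {
  data.frame(stage = stage, locus = locus, action = action,
             reason = reason, stringsAsFactors = FALSE)
}

#' Run the discovery workflow on a cohort
#'
#' QC -> per-trait eQTLWAS over every variant -> Bonferroni gate at
#' alpha / (variants x traits) -> fine-mapping of the 1-Mb region around
#' each gated lead SNP (LD from the cohort's own dosages) -> single
#' instrument MR per gene x tissue x trait with the Steiger directionality
#' test -> multiple-trait colocalization per gene x CpG combination around
#' each lead SNP. A failure in one locus branch is logged and the run
#' continues for the others. Deterministic given cohort and config.
#'
#' @param config a [pipeline_config()].
#' @param cohort a [simulate_cohort()] result.
#' @return an object of class \code{run_report}: list with \code{scheduled}
#'   (eQTLWAS test count), \code{threshold}, \code{n_signals},
#'   \code{leads}, per-stage outputs (\code{assoc}, \code{finemap},
#'   \code{mr}, \code{moloc}), \code{mr_scheduled}, \code{mr_threshold},
#'   \code{log} (stage/locus/action/reason rows) and the config
#'   \code{fingerprint}.
#' @export
run_discovery <- function(config, cohort) {
  stopifnot(inherits(config, "pipeline_config"), inherits(cohort, "cohort"))
  n_instruments <- ncol(cohort$dosages)
  traits <- intersect(config$traits, names(cohort$traits))
  if (n_instruments == 0L || length(traits) == 0L)
    stop("configuration error: instruments and traits must be nonempty")
  logs <- list()
  covars <- data.frame(age = cohort$age, sex = cohort$sex)
  qc <- qc_config(sd_limit = config$sd_limit, info_min = config$info_min,
                  maf_min = config$maf_assoc)

  # stage 1: QC + eQTLWAS per trait
  scheduled <- n_instruments * length(traits)
  threshold <- bonferroni_threshold(scheduled, config$alpha)
  assoc_records <- list()
  for (tr in traits) {
    cleaned <- clean_phenotypes(cohort$traits[[tr]], qc, tr)
    if (cleaned$report$n_removed > 0)
      logs[[length(logs) + 1L]] <- log_entry("qc", tr, "outliers_removed",
                                             cleaned$report$n_removed)
    assoc_records[[tr]] <- run_eqtlwas(cohort$dosages, cleaned$values,
                                       covars, cohort$variant_meta,
                                       trait = tr)
  }
  assoc_all <- do.call(rbind, assoc_records)
  hits <- assoc_all[!is.na(assoc_all$p) & assoc_all$p < threshold, ,
                    drop = FALSE]
  leads <- lead_snps(hits, window = config$window)

  # stage 2: fine-mapping around each lead
  finemap_results <- list()
  if ("finemap" %in% config$stages && nrow(leads) > 0) {
    R <- ld_matrix(cohort$dosages)
    for (i in seq_len(nrow(leads))) {
      lead <- leads[i, ]
      key <- paste(lead$variant_id, lead$trait, sep = ":")
      finemap_results[[key]] <- tryCatch({
        rec <- assoc_records[[lead$trait]]
        in_win <- !is.na(rec$pos) &
          abs(rec$pos - lead$pos) <= config$window & !is.na(rec$beta)
        rec <- rec[in_win, , drop = FALSE]
        reg <- finemap_region(rec$variant_id, rec$beta / rec$se,
                              R[rec$variant_id, rec$variant_id],
                              n = stats::median(rec$n),
                              center = lead$variant_id, pos = rec$pos,
                              window = config$window)
        enumerate_posteriors(reg, k_max = config$k_max,
                             prior_sd = config$finemap_prior_sd)
      }, error = function(e) {
        logs[[length(logs) + 1L]] <<- log_entry("finemap", key, "failed",
                                                conditionMessage(e))
        NULL
      })
    }
  }

  # stage 3: tissue-specific MR with Steiger
  mr_results <- NULL
  mr_scheduled <- 0L
  mr_threshold <- NA_real_
  eqtl <- NULL
  if ("mr" %in% config$stages) {
    eqtl <- cohort_summary_stats(cohort, "eqtl")
    instruments <- select_instruments(eqtl, config$instrument_p,
                                      config$window, cohort$gene_meta)
    if (nrow(instruments) == 0L) {
      logs[[length(logs) + 1L]] <- log_entry("mr", "all", "skipped",
                                             "no instrument passed")
    } else {
      per_trait <- lapply(traits, function(tr)
        mr_run(instruments, assoc_records[[tr]]))
      mr_results <- do.call(rbind, per_trait)
      mr_scheduled <- nrow(instruments) * length(traits)
      mr_threshold <- bonferroni_threshold(mr_scheduled, config$alpha)
      mr_results$pass_gate <- !is.na(mr_results$p) &
        mr_results$p < mr_threshold
    }
  }

  # stage 4: moloc per gene x CpG combination around each lead
  moloc_results <- list()
  if ("moloc" %in% config$stages && nrow(leads) > 0) {
    if (is.null(eqtl)) eqtl <- cohort_summary_stats(cohort, "eqtl")
    mqtl <- cohort_summary_stats(cohort, "mqtl")
    genes <- stats::setNames(cohort$gene_meta$tss, cohort$gene_meta$gene)
    cpgs <- stats::setNames(cohort$cpg_meta$pos, cohort$cpg_meta$cpg)
    for (i in seq_len(nrow(leads))) {
      lead <- leads[i, ]
      combos <- map_cpg_to_genes(lead$pos, cpgs, genes, config$window)
      for (k in seq_len(nrow(combos))) {
        gene <- combos$gene[k]; cpg <- combos$cpg[k]
        for (tis in intersect(config$tissues,
                              unique(eqtl$tissue))) {
          key <- paste(lead$variant_id, lead$trait, gene, cpg, tis,
                       sep = ":")
          res <- tryCatch(
            moloc_region(
              g = assoc_records[[lead$trait]],
              e = eqtl[eqtl$gene == gene & eqtl$tissue == tis, ,
                       drop = FALSE],
              m = mqtl[mqtl$cpg == cpg, , drop = FALSE],
              priors = config$priors, min_snps = config$min_snps,
              maf_min = config$maf_moloc,
              prior_sd = config$moloc_prior_sd,
              ppa_threshold = config$ppa_threshold),
            error = function(e) {
              logs[[length(logs) + 1L]] <<- log_entry("moloc", key,
                                                      "failed",
                                                      conditionMessage(e))
              NULL
            })
          if (!is.null(res)) {
            if (res$status != "ok")
              logs[[length(logs) + 1L]] <- log_entry("moloc", key,
                                                     "skipped", res$reason)
            moloc_results[[key]] <- res
          }
        }
      }
    }
  }

  structure(list(mode = "discovery", scheduled = scheduled,
                 threshold = threshold, n_signals = nrow(hits),
                 leads = leads, assoc = assoc_all,
                 finemap = finemap_results, mr = mr_results,
                 mr_scheduled = mr_scheduled, mr_threshold = mr_threshold,
                 moloc = moloc_results,
                 log = if (length(logs)) do.call(rbind, logs) else
                   log_entry(character(0), character(0), character(0),
                             character(0)),
                 fingerprint = config$fingerprint, config = config),
            class = "run_report")
}

#' Run the genome-wide scan mode
#'
#' For each lead eQTL per gene x tissue, looks its variant up in every GWAS
#' (substituting a proxy at r^2 >= \code{r2_proxy} when absent), gates the
#' GWAS associations by Bonferroni at alpha / total lookups, and follows
#' survivors with MR (Wald + Steiger) and multiple-trait colocalization. A
#' finding is reported when the association survives multiple testing AND
#' the summed G-E PPA reaches the decision threshold. Fine-mapping is
#' deliberately not run in this mode: it would require individual-level LD,
#' and reference-panel LD inflates false positives.
#'
#' @param config a [pipeline_config()].
#' @param eqtl_catalog lead-eQTL summary statistics with columns
#'   \code{gene}, \code{tissue} plus the standard columns.
#' @param gwas named list of per-trait GWAS summary-statistics tables.
#' @param mqtl mQTL summary statistics with a \code{cpg} column
#'   (\code{NULL} runs two-trait colocalization).
#' @param ld_source dosage or LD matrix covering the loci, for proxies.
#' @return an object of class \code{run_report} with \code{scheduled}
#'   (total lookups), \code{threshold}, \code{results} (one row per
#'   gene x tissue x trait lookup) and \code{findings} (gated +
#'   colocalized subset).
#' @export
run_genomewide <- function(config, eqtl_catalog, gwas, mqtl = NULL,
                           ld_source = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(names(gwas)) || any(names(gwas) == ""))
    stop("gwas must be a named list of per-trait summary tables")
  keys <- unique(eqtl_catalog[, c("gene", "tissue")])
  scheduled <- nrow(keys) * length(gwas)
  if (scheduled == 0L) stop("configuration error: no lookups scheduled")
  threshold <- bonferroni_threshold(scheduled, config$alpha)
  logs <- list()
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    gene <- keys$gene[i]; tis <- keys$tissue[i]
    cat_rows <- eqtl_catalog[eqtl_catalog$gene == gene &
                               eqtl_catalog$tissue == tis, , drop = FALSE]
    inst <- cat_rows[order(cat_rows$p, cat_rows$variant_id)[1], ,
                     drop = FALSE]
    for (tr in names(gwas)) {
      grec <- gwas[[tr]]
      key <- paste(gene, tis, tr, sep = ":")
      row <- data.frame(gene = gene, tissue = tis, outcome = tr,
                        variant_id = inst$variant_id,
                        proxy_used = NA_character_, gwas_p = NA_real_,
                        pass_gate = FALSE, beta_mr = NA_real_,
                        se_mr = NA_real_, p_mr = NA_real_,
                        steiger_p = NA_real_, direction_ok = NA,
                        summed_ge = NA_real_, gem = NA_real_,
                        finding = FALSE, note = NA_character_,
                        stringsAsFactors = FALSE)
      hit <- grec[grec$variant_id == inst$variant_id, , drop = FALSE]
      lookup <- inst
      if (nrow(hit) == 0L && !is.null(ld_source)) {
        px <- tryCatch(find_proxy(inst$variant_id, ld_source,
                                  grec$variant_id, config$r2_proxy),
                       error = function(e) list(proxy = NA_character_))
        if (!is.na(px$proxy)) {
          hit <- grec[grec$variant_id == px$proxy, , drop = FALSE]
          row$proxy_used <- px$proxy
          lookup <- cat_rows[cat_rows$variant_id == px$proxy, ,
                             drop = FALSE]
          if (nrow(lookup) == 0L) lookup <- inst  # proxy absent from eQTL
        }
      }
      if (nrow(hit) == 0L) {
        row$note <- "variant not found (no proxy at r2 threshold)"
        logs[[length(logs) + 1L]] <- log_entry("lookup", key, "missing",
                                               row$note)
        rows[[length(rows) + 1L]] <- row
        next
      }
      row$gwas_p <- hit$p[1]
      row$pass_gate <- !is.na(row$gwas_p) && row$gwas_p < threshold
      if (row$pass_gate) {
        branch <- tryCatch({
          pair <- harmonize(lookup[1, , drop = FALSE],
                            hit[1, , drop = FALSE])
          if (pair$palindromic_status != "dropped") {
            w <- wald_ratio(pair)
            s <- steiger_test(pair)
            row$beta_mr <- w$beta_mr; row$se_mr <- w$se_mr
            row$p_mr <- w$p
            row$steiger_p <- s$p; row$direction_ok <- s$direction_ok
          } else row$note <- "dropped: ambiguous palindromic alleles"
          e_rec <- cat_rows
          m_rec <- if (!is.null(mqtl)) {
            near <- mqtl[!is.na(mqtl$pos) &
                           abs(mqtl$pos - inst$pos) <= config$window, ,
                         drop = FALSE]
            if (nrow(near)) near[near$cpg == near$cpg[1], , drop = FALSE]
            else NULL
          } else NULL
          mres <- moloc_region(g = grec, e = e_rec, m = m_rec,
                               priors = config$priors,
                               min_snps = config$min_snps,
                               maf_min = config$maf_moloc,
                               prior_sd = config$moloc_prior_sd,
                               ppa_threshold = config$ppa_threshold)
          if (mres$status == "ok") {
            row$summed_ge <- mres$summed_ge
            row$gem <- mres$gem
            row$finding <- isTRUE(mres$summed_ge >= config$ppa_threshold)
          } else {
            logs[[length(logs) + 1L]] <- log_entry("moloc", key, "skipped",
                                                   mres$reason)
          }
          row
        }, error = function(e) {
          logs[[length(logs) + 1L]] <<- log_entry("branch", key, "failed",
                                                  conditionMessage(e))
          row$note <- conditionMessage(e)
          row
        })
        row <- branch
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, rows)
  structure(list(mode = "genomewide", scheduled = scheduled,
                 threshold = threshold,
                 n_signals = sum(results$pass_gate),
                 results = results,
                 findings = results[results$finding, , drop = FALSE],
                 log = if (length(logs)) do.call(rbind, logs) else
                   log_entry(character(0), character(0), character(0),
                             character(0)),
                 fingerprint = config$fingerprint, config = config),
            class = "run_report")
}

#' Write a run report
#'
#' Writes a machine-readable key/value TSV (\code{report.tsv}, byte-stable
#' across identical reruns), the stage log (\code{log.tsv}), stage output
#' tables, and a human-readable \code{report.txt}. Every number in the
#' report is recomputable from the stage outputs.
#'
#' @param report a [run_discovery()] or [run_genomewide()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  disp <- function(x) format(signif(x, 2))  # display: 2 significant figures
  kv <- rbind(
    data.frame(key = "mode", value = report$mode),
    data.frame(key = "scheduled_tests", value = format(report$scheduled)),
    data.frame(key = "threshold",
               value = format(report$threshold, digits = 15)),
    data.frame(key = "threshold_display", value = disp(report$threshold)),
    data.frame(key = "n_signals", value = format(report$n_signals)),
    data.frame(key = "fingerprint", value = report$fingerprint))
  if (report$mode == "discovery") {
    kv <- rbind(kv,
      data.frame(key = "n_lead_snps", value = format(nrow(report$leads))),
      data.frame(key = "mr_scheduled", value = format(report$mr_scheduled)),
      data.frame(key = "mr_threshold",
                 value = format(report$mr_threshold, digits = 15)))
  }
  utils::write.table(kv, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$log, file.path(dir, "log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$assoc))
    write_summary_stats(report$assoc, file.path(dir, "assoc.tsv"))
  if (!is.null(report$mr))
    utils::write.table(report$mr, file.path(dir, "mr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (report$mode == "genomewide")
    utils::write.table(report$results, file.path(dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- c(sprintf("run mode: %s", report$mode),
           sprintf("scheduled tests: %d", report$scheduled),
           sprintf("Bonferroni threshold: %s (full precision %.6g)",
                   disp(report$threshold), report$threshold),
           sprintf("signals passing the gate: %d", report$n_signals),
           sprintf("config fingerprint: %s", report$fingerprint))
  if (nrow(report$log) > 0)
    txt <- c(txt, "", "log:", sprintf("  [%s] %s %s %s", report$log$stage,
                                      report$log$locus, report$log$action,
                                      report$log$reason))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("%s run: %d scheduled tests, threshold %.3g, %d signal(s)\n",
              x$mode, x$scheduled, x$threshold, x$n_signals))
  invisible(x)
}
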