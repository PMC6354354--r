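# Phenotype QC, variant filtering, the adjusted association scan, and
# multiple-testing gating.

test_that("outlier cleaning removes exactly the values beyond the cut", {
  set.seed(42)
  x <- rnorm(1000)
  x[c(1000, 500)] <- c(10, -10)  # constructed to be the only |z| > 4 values
  stopifnot(max(abs(scale(x[-c(500, 1000)]))) < 4)
  res <- clean_phenotypes(x, qc_config())
  expect_setequal(res$removed, c(500, 1000))
  # direct recomputation of the rule
  expect_setequal(res$removed,
                  which(abs(x - mean(x)) > 4 * sd(x)))
  # no-op when everything is inside the cut
  y <- rnorm(100)
  y <- pmin(pmax(y, -2), 2)
  res2 <- clean_phenotypes(y, qc_config())
  expect_identical(res2$values, y)
  expect_length(res2$removed, 0)
})

test_that("cleaning is a single pass and therefore idempotent", {
  set.seed(7)
  x <- c(rnorm(500), 8, -9)
  once <- clean_phenotypes(x, qc_config())
  twice <- clean_phenotypes(once$values, qc_config())
  expect_identical(once$values, twice$values)
  expect_length(twice$removed, 0)
})

test_that("degenerate inputs to cleaning are handled", {
  expect_identical(clean_phenotypes(rep(5, 50), qc_config())$removed,
                   integer(0))  # SD = 0: nothing removed
  expect_error(clean_phenotypes(rep(NA_real_, 20), qc_config()), "missing")
  # log-flagged trait is scanned on the log scale
  z <- exp(rnorm(100))
  cfg <- qc_config(log_flags = c(trait = TRUE))
  res <- clean_phenotypes(z, cfg, "trait")
  expect_equal(res$values[!is.na(res$values)],
               log(z)[!is.na(res$values)])
  expect_true(res$report$log_applied)
})

test_that("variant filters apply the info and MAF boundary rules", {
  rec <- rbind(make_record("a", info = 0.80, eaf = 0.02),
               make_record("b", info = 0.79, eaf = 0.3),
               make_record("c", info = NA, eaf = 0.99),
               make_record("d", info = NA, eaf = 0.5),
               make_record("e", info = 0.95, eaf = 0.01))
  out <- filter_variants(rec, qc_config())
  expect_setequal(out$records$variant_id, c("a", "d"))
  expect_equal(unname(out$counts["missing_info"]), 1)  # d passes unscored
  # idempotent
  again <- filter_variants(out$records, qc_config())
  expect_identical(again$records, out$records)
  # malformed rows are skipped with a warning, counted
  bad <- rbind(rec, make_record("f", eaf = NA))
  expect_warning(out2 <- filter_variants(bad, qc_config()), "malformed")
  expect_equal(unname(out2$counts["malformed"]), 1)
})

test_that("the adjusted scan matches lm and flags degenerate designs", {
  ch <- small_cohort(n = 500, seed = 21)
  covars <- data.frame(age = ch$age, sex = ch$sex)
  rec <- run_eqtlwas(ch$dosages, ch$traits$trait, covars, ch$variant_meta)
  # cross-check one variant against a full lm fit
  j <- 4
  fit <- summary(lm(ch$traits$trait ~ ch$dosages[, j] + ch$age + ch$sex))
  expect_equal(rec$beta[j], unname(fit$coefficients[2, 1]), tolerance = 1e-10)
  expect_equal(rec$se[j], unname(fit$coefficients[2, 2]), tolerance = 1e-10)
  expect_equal(rec$p[j], unname(fit$coefficients[2, 4]), tolerance = 1e-10)

  # monomorphic variant: record emitted, run continues
  dos <- ch$dosages
  dos[, 2] <- 0L
  rec2 <- run_eqtlwas(dos, ch$traits$trait, covars, ch$variant_meta)
  expect_true(is.na(rec2$beta[2]))
  expect_match(rec2$note[2], "monomorphic")
  expect_false(anyNA(rec2$beta[-2]))

  # missing-data path agrees with the complete-data path
  dos_na <- ch$dosages
  dos_na[1, 1] <- NA
  rec3 <- run_eqtlwas(dos_na, ch$traits$trait, covars, ch$variant_meta)
  fit3 <- summary(lm(ch$traits$trait[-1] ~ ch$dosages[-1, 1] + ch$age[-1] +
                       ch$sex[-1]))
  expect_equal(rec3$beta[1], unname(fit3$coefficients[2, 1]),
               tolerance = 1e-10)
  expect_equal(rec3$se[1], unname(fit3$coefficients[2, 2]),
               tolerance = 1e-10)
})

test_that("the scan recovers the generative SNP-trait slope", {
  sp <- scenario_spec(1, n_individuals = 20000, n_snps = 4, seed = 77)
  ch <- simulate_cohort(sp)
  rec <- run_eqtlwas(ch$dosages, ch$traits$trait,
                     data.frame(age = ch$age, sex = ch$sex),
                     ch$variant_meta)
  snp <- sp$eqtl_effects$GENE1$snp
  truth <- sp$eqtl_effects$GENE1$beta * sp$mediation_effects["GENE1"]
  expect_lt(abs(rec$beta[snp] - truth), 3 * rec$se[snp])
})

test_that("Bonferroni thresholds reproduce the study arithmetic", {
  expect_equal(bonferroni_threshold(273742), 0.05 / 273742)
  expect_equal(signif(bonferroni_threshold(273742), 2), 1.8e-7)
  expect_equal(signif(bonferroni_threshold(54), 2), 9.3e-4)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_error(bonferroni_threshold(0), "positive")
  # strictly decreasing in the number of tests
  ns <- c(1, 10, 100, 54, 273742)
  th <- sapply(sort(ns), bonferroni_threshold)
  expect_true(all(diff(th) < 0))
})

test_that("signal counting distinguishes signals from unique lead SNPs", {
  tab <- eqtlwas_signals()
  cnt <- count_signals(tab)
  expect_equal(cnt$n_signals, 11)
  expect_equal(cnt$n_unique_lead_snps, 8)
  expect_equal(count_signals(tab[0, ], 0.05),
               list(n_signals = 0, n_unique_lead_snps = 0))
  expect_equal(count_signals(make_record(p = 1e-9), 1e-7),
               list(n_signals = 1, n_unique_lead_snps = 1))
})

test_that("summary statistics round-trip through the TSV format", {
  ch <- small_cohort(n = 200, n_snps = 5, seed = 4)
  rec <- run_eqtlwas(ch$dosages, ch$traits$trait,
                     data.frame(age = ch$age, sex = ch$sex),
                     ch$variant_meta)
  path <- tempfile(fileext = ".tsv")
  write_summary_stats(rec, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(header[1:12],
                   c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "p", "n",
                     "trait", "info"))
  back <- read_summary_stats(path)
  expect_equal(back$beta, rec$beta, tolerance = 1e-12)
  expect_identical(back$variant_id, rec$variant_id)

  mt <- manhattan_table(rec, 1e-3)
  expect_identical(nrow(mt), nrow(rec))
  expect_equal(mt$neg_log10_p, -log10(rec$p))
})

test_that("lead-SNP clumping keeps the smallest p per locus", {
  rec <- rbind(make_record("rs_b", pos = 1e6, p = 1e-10),
               make_record("rs_a", pos = 1.2e6, p = 1e-10),
               make_record("rs_c", pos = 1.1e6, p = 1e-8),
               make_record("rs_d", pos = 5e6, p = 1e-9))
  leads <- lead_snps(rec, window = 1e6)
  # tie at 1e-10 broken lexicographically; rs_c absorbed; rs_d separate
  expect_identical(leads$variant_id, c("rs_a", "rs_d"))
})
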