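# Two-sample MR: instrument selection rules, harmonization, Wald ratio,
# Steiger directionality, proxy lookup.

test_that("instrument selection applies the cis-window and p rules", {
  tss <- c(GENE1 = 2e6)
  base <- make_record("rs1", pos = 2e6, p = 1e-6)
  base$gene <- "GENE1"; base$tissue <- "liver"
  at_edge <- base; at_edge$variant_id <- "rs_edge"; at_edge$pos <- 3e6
  beyond <- base; beyond$variant_id <- "rs_out"; beyond$pos <- 3e6 + 1
  at_p <- base; at_p$variant_id <- "rs_p"; at_p$p <- 1e-4
  stronger <- base; stronger$variant_id <- "rs_best"; stronger$p <- 1e-8
  rec <- rbind(base, at_edge, beyond, at_p, stronger)
  out <- select_instruments(rec, tss = tss)
  # inclusive at exactly 1 Mb, strict at p = 1e-4, lead = smallest p
  expect_equal(nrow(out), 1)
  expect_identical(out$variant_id, "rs_best")
  sel <- select_instruments(rbind(at_edge, beyond), tss = tss)
  expect_identical(sel$variant_id, "rs_edge")
  expect_equal(nrow(select_instruments(at_p, tss = tss)), 0)
  # p ties broken by variant_id
  tie1 <- base; tie1$variant_id <- "rs_b"
  tie2 <- base; tie2$variant_id <- "rs_a"
  expect_identical(select_instruments(rbind(tie1, tie2), tss = tss)$variant_id,
                   "rs_a")
})

test_that("harmonization aligns effect alleles and flips signs", {
  exp_rec <- make_record("rs1", effect_allele = "A", other_allele = "G",
                         beta = 0.2, eaf = 0.3)
  out_rec <- make_record("rs1", effect_allele = "G", other_allele = "A",
                         beta = -0.1, eaf = 0.7)
  pair <- harmonize(exp_rec, out_rec)
  expect_equal(pair$outcome$beta, 0.1)
  expect_equal(pair$outcome$eaf, 0.3)
  expect_true(pair$flips_applied)
  expect_identical(pair$outcome$effect_allele, "A")

  # already aligned: untouched
  aligned <- harmonize(exp_rec, make_record("rs1", effect_allele = "A",
                                            other_allele = "G", beta = 0.1))
  expect_false(aligned$flips_applied)

  # strand flip: outcome reported on the other strand (T/C vs A/G)
  strand <- harmonize(exp_rec, make_record("rs1", effect_allele = "T",
                                           other_allele = "C", beta = 0.1))
  expect_equal(strand$outcome$beta, 0.1)
  expect_identical(strand$outcome$effect_allele, "A")
  # strand flip + allele swap
  both <- harmonize(exp_rec, make_record("rs1", effect_allele = "C",
                                         other_allele = "T", beta = 0.1))
  expect_equal(both$outcome$beta, -0.1)

  # irreconcilable allele sets
  expect_error(harmonize(exp_rec, make_record("rs1", effect_allele = "A",
                                              other_allele = "C")),
               "cannot harmonize")
})

test_that("palindromic pairs resolve by frequency or drop", {
  exp_pal <- make_record("rs1", effect_allele = "A", other_allele = "T",
                         beta = 0.2, eaf = 0.2)
  # both minor: aligned without flip
  ok <- harmonize(exp_pal, make_record("rs1", effect_allele = "A",
                                       other_allele = "T", beta = 0.1,
                                       eaf = 0.21))
  expect_identical(ok$palindromic_status, "resolved")
  expect_false(ok$flips_applied)
  # frequency sides disagree: flip
  flip <- harmonize(exp_pal, make_record("rs1", effect_allele = "A",
                                         other_allele = "T", beta = 0.1,
                                         eaf = 0.79))
  expect_true(flip$flips_applied)
  expect_equal(flip$outcome$beta, -0.1)
  # ambiguous near 0.5: dropped
  amb <- harmonize(make_record("rs1", effect_allele = "A",
                               other_allele = "T", eaf = 0.5),
                   make_record("rs1", effect_allele = "A",
                               other_allele = "T", eaf = 0.49))
  expect_identical(amb$palindromic_status, "dropped")
  expect_error(wald_ratio(amb), "dropped")
})

test_that("the Wald ratio and its delta-method error follow the formulas", {
  pair <- harmonize(make_record("rs1", beta = 0.5, se = 0.05),
                    make_record("rs1", beta = 0.25, se = 0.05))
  w <- wald_ratio(pair)
  expect_equal(w$beta_mr, 0.5)
  expect_equal(w$se_mr, 0.1)
  expect_equal(w$p, 2 * pnorm(5, lower.tail = FALSE))
  # zero outcome effect gives a zero estimate
  null_pair <- harmonize(make_record("rs1", beta = 0.5),
                         make_record("rs1", beta = 0))
  expect_equal(wald_ratio(null_pair)$beta_mr, 0)
  # undefined when the exposure effect vanishes
  zero_exp <- harmonize(make_record("rs1", beta = 0),
                        make_record("rs1", beta = 0.1))
  expect_error(wald_ratio(zero_exp), "undefined")
  # second-order SE adds the exposure-uncertainty term
  w2 <- wald_ratio(pair, second_order = TRUE)
  expect_equal(w2$se_mr,
               sqrt(0.05^2 / 0.5^2 + 0.25^2 * 0.05^2 / 0.5^4))
  expect_gt(w2$se_mr, w$se_mr)
})

test_that("Wald ratio is equivariant under exposure rescaling", {
  k <- 3.7
  p1 <- harmonize(make_record("rs1", beta = 0.4, se = 0.03),
                  make_record("rs1", beta = 0.12, se = 0.02))
  p2 <- harmonize(make_record("rs1", beta = 0.4 * k, se = 0.03 * k),
                  make_record("rs1", beta = 0.12, se = 0.02))
  w1 <- wald_ratio(p1); w2 <- wald_ratio(p2)
  expect_equal(w2$beta_mr, w1$beta_mr / k)
  expect_equal(w2$se_mr, w1$se_mr / k)
})

test_that("the Steiger test orients the causal arrow", {
  # equal correlations: z = 0, p = 1
  pair_eq <- harmonize(make_record("rs1", beta = 0.1, se = 0.02, n = 5000),
                       make_record("rs1", beta = 0.1, se = 0.02, n = 5000))
  s_eq <- steiger_test(pair_eq)
  expect_equal(s_eq$z_statistic, 0)
  expect_equal(s_eq$p, 1)

  # strong exposure, weak outcome: clear direction (evaluate the Fisher-z
  # formula directly as the oracle)
  n_exp <- 5000; n_out <- 50000
  r_exp <- 0.10; r_out <- 0.01
  t_exp <- r_exp * sqrt((n_exp - 2) / (1 - r_exp^2))
  t_out <- r_out * sqrt((n_out - 2) / (1 - r_out^2))
  pair <- harmonize(make_record("rs1", beta = t_exp, se = 1, n = n_exp),
                    make_record("rs1", beta = t_out, se = 1, n = n_out))
  s <- steiger_test(pair)
  expect_true(s$direction_ok)
  expect_lt(s$p, 1e-6)
  expect_equal(s$r2_exposure, r_exp^2, tolerance = 1e-10)
  z_oracle <- (atanh(r_exp) - atanh(r_out)) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  expect_equal(s$z_statistic, z_oracle, tolerance = 1e-10)

  # swapping exposure and outcome negates the verdict, |z| unchanged
  s_rev <- steiger_test(harmonize(pair$outcome, pair$exposure))
  expect_false(s_rev$direction_ok)
  expect_equal(abs(s_rev$z_statistic), abs(s$z_statistic), tolerance = 1e-10)
})

test_that("Steiger verdicts are near-certain under scenario-1 data", {
  ok <- sapply(1:40, function(r) {
    sp <- scenario_spec(1, n_individuals = 5000, n_snps = 2,
                        seed = 5000 + r)
    ch <- simulate_cohort(sp)
    cols <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
              "eaf", "beta", "se", "p", "n", "trait", "info")
    e <- cohort_summary_stats(ch, "eqtl")
    g <- cohort_summary_stats(ch, "gwas")
    i <- sp$eqtl_effects$GENE1$snp
    steiger_test(harmonize(e[e$gene == "GENE1", cols][i, ],
                           g[i, cols]))$direction_ok
  })
  expect_gte(mean(ok), 0.95)
})

test_that("proxy lookup honors the r-squared threshold and max rule", {
  set.seed(31)
  g <- simulate_genotypes(4000, rep(0.3, 6), ld_rho = 0.9, seed = 31)
  g <- cbind(g, dup = g[, 1])  # perfect-LD duplicate of snp_01
  # perfect duplicate dominates
  px <- find_proxy("snp_01", g, available = c("dup", "snp_02"))
  expect_identical(px$proxy, "dup")
  expect_equal(px$r2, 1)
  # max-r2 rule among qualifying candidates
  R <- matrix(c(1, .95, .92, .95, 1, .9, .92, .9, 1), 3,
              dimnames = list(c("t", "a", "b"), c("t", "a", "b")))
  expect_identical(find_proxy("t", R, c("a", "b"))$proxy, "a")
  # below threshold: none
  R2 <- matrix(c(1, sqrt(0.79), sqrt(0.79), 1), 2,
               dimnames = list(c("t", "a"), c("t", "a")))
  expect_true(is.na(find_proxy("t", R2, "a")$proxy))
  # target absent from the LD source
  expect_error(find_proxy("missing", R, "a"), "absent")
})

test_that("mr_run assembles the results table and isolates failures", {
  sp <- scenario_spec(1, n_individuals = 4000, n_snps = 6, seed = 13)
  ch <- simulate_cohort(sp)
  eqtl <- cohort_summary_stats(ch, "eqtl")
  gwas <- cohort_summary_stats(ch, "gwas")
  inst <- select_instruments(eqtl, tss = ch$gene_meta)
  res <- mr_run(inst, gwas)
  expect_identical(res$exposure, "GENE1")
  expect_false(is.na(res$beta_mr))
  expect_false(is.na(res$steiger_p))
  # instrument absent from the outcome with no proxy source
  inst2 <- inst; inst2$variant_id <- "rs_absent"
  res2 <- mr_run(inst2, gwas)
  expect_true(is.na(res2$beta_mr))
  expect_match(res2$note, "absent")
  vt <- mr_volcano_table(res)
  expect_identical(names(vt), c("exposure", "tissue", "outcome", "beta_mr",
                                "neg_log10_p"))
})
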