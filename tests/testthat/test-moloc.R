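# Multiple-trait colocalization: ABF against quadrature, configuration
# combinatorics, PPA normalization, oracle equivalence, decision rules,
# gene-centric CpG mapping.

test_that("the Wakefield log ABF matches numerical integration", {
  beta <- 0.5; se <- 0.1; W <- 0.15
  num <- integrate(function(b) dnorm(beta, b, se) * dnorm(b, 0, W),
                   -Inf, Inf, rel.tol = 1e-12)$value
  oracle <- log(num / dnorm(beta, 0, se))
  expect_equal(wakefield_log_abf(beta, se, W), oracle, tolerance = 1e-8)

  # z = 0: log ABF = 0.5 * log(V / (V + W)) < 0
  expect_equal(wakefield_log_abf(0, 0.1, 0.15),
               0.5 * log(0.1^2 / (0.1^2 + 0.15^2)))
  expect_lt(wakefield_log_abf(0, 0.1, 0.15), 0)
  # degenerate-prior limit: evidence vanishes
  expect_equal(wakefield_log_abf(0.5, 0.1, 1e-8), 0, tolerance = 1e-4)
  expect_error(wakefield_log_abf(0.1, 0), "positive")
})

test_that("configuration enumeration yields the exact counts", {
  expect_length(enumerate_configurations(3), 15)
  two <- enumerate_configurations(2)
  expect_length(two, 5)
  expect_setequal(vapply(two, `[[`, character(1), "label"),
                  c("null", "G", "E", "E.G", "GE"))
  expect_length(enumerate_configurations(1), 2)
  expect_length(enumerate_configurations(4), 52)
  expect_error(enumerate_configurations(5), "1..4")
  # deterministic ordering
  l1 <- vapply(enumerate_configurations(3), `[[`, character(1), "label")
  l2 <- vapply(enumerate_configurations(3), `[[`, character(1), "label")
  expect_identical(l1, l2)
  expect_identical(l1[1], "null")
})

test_that("region PPAs match the brute-force assignment oracle", {
  set.seed(5)
  m <- 12
  priors <- c(1e-4, 1e-6, 1e-7)
  for (rep in 1:3) {
    log_abf <- matrix(rnorm(m * 3, mean = c(2, 1, 0), sd = 3), m, 3,
                      byrow = TRUE)
    colnames(log_abf) <- c("G", "E", "M")
    configs <- enumerate_configurations(3)
    ev <- vapply(configs, function(cf)
      tissuemr:::config_log_evidence(cf$groups, log_abf, priors),
      numeric(1))
    ppa <- exp(ev - lse(ev))
    names(ppa) <- vapply(configs, `[[`, character(1), "label")
    expect_equal(ppa, oracle_moloc_ppa(log_abf, priors), tolerance = 1e-10)
    expect_equal(sum(ppa), 1, tolerance = 1e-8)
  }
})

test_that("moloc_region normalizes, skips small regions, detects the null", {
  set.seed(9)
  ids <- sprintf("v%03d", 1:60)
  mk <- function(beta) {
    rec <- make_record(ids, pos = 1e6 + 1:60, beta = beta,
                       se = 0.05, eaf = 0.3, n = 5000)
    rec
  }
  g <- mk(rnorm(60, 0, 0.01)); e <- mk(rnorm(60, 0, 0.01))
  m <- mk(rnorm(60, 0, 0.01))
  res <- moloc_region(g, e, m)
  expect_identical(res$status, "ok")
  expect_equal(sum(res$ppa), 1, tolerance = 1e-8)
  expect_identical(names(which.max(res$ppa)), "null")
  expect_gte(res$summed_ge, res$gem)  # summed rule dominates all-share

  # 49 common SNPs: structured skip, not an exception
  res49 <- moloc_region(g[1:49, ], e, m)
  expect_identical(res49$status, "insufficient_snps")
  expect_match(res49$reason, "insufficient SNPs")
  expect_equal(res49$n_snps_used, 49)

  # MAF filter is inclusive at 0.05
  g2 <- g; g2$eaf <- 0.05
  expect_identical(moloc_region(g2, e, m)$status, "ok")
  g3 <- g; g3$eaf <- 0.049
  expect_identical(moloc_region(g3, e, m)$status, "insufficient_snps")
})

test_that("a shared causal SNP drives the all-share configuration", {
  sp <- scenario_spec(1, n_individuals = 20000, n_snps = 100, seed = 11)
  ch <- simulate_cohort(sp)
  g <- cohort_summary_stats(ch, "gwas")
  e <- cohort_summary_stats(ch, "eqtl")
  m <- cohort_summary_stats(ch, "mqtl")
  res <- moloc_region(g, e[e$gene == "GENE1", ], m[m$cpg == "cpg1", ])
  expect_identical(res$status, "ok")
  expect_gte(res$gem, 0.8)
  expect_true(res$decision_gem)
  expect_equal(res$n_snps_used, 100)
})

test_that("summed PPAs follow their definitions", {
  sp <- scenario_spec(1, n_individuals = 5000, n_snps = 60, seed = 23)
  ch <- simulate_cohort(sp)
  g <- cohort_summary_stats(ch, "gwas")
  e <- cohort_summary_stats(ch, "eqtl")
  m <- cohort_summary_stats(ch, "mqtl")
  res <- moloc_region(g, e[e$gene == "GENE1", ], m[m$cpg == "cpg1", ])
  ppa <- res$ppa
  expect_equal(summed_ppa(res, c("G", "E")),
               unname(ppa["GE"] + ppa["GE.M"] + ppa["GEM"]),
               tolerance = 1e-12)
  expect_equal(summed_ppa(res, c("G", "E", "M")), unname(ppa["GEM"]),
               tolerance = 1e-12)
  expect_error(summed_ppa(res, "X"), "unknown trait")
  expect_error(summed_ppa(res, character(0)), "nonempty")
})

test_that("alignment flips mismatched outcome strands before scoring", {
  sp <- scenario_spec(1, n_individuals = 8000, n_snps = 60, seed = 41)
  ch <- simulate_cohort(sp)
  g <- cohort_summary_stats(ch, "gwas")
  e <- cohort_summary_stats(ch, "eqtl")
  m <- cohort_summary_stats(ch, "mqtl")
  e1 <- e[e$gene == "GENE1", ]
  # swap alleles and negate betas on half the expression records: the
  # aligned analysis must be invariant
  swap <- seq(1, 60, by = 2)
  tmp <- e1$effect_allele[swap]
  e1$effect_allele[swap] <- e1$other_allele[swap]
  e1$other_allele[swap] <- tmp
  e1$beta[swap] <- -e1$beta[swap]
  e1$eaf[swap] <- 1 - e1$eaf[swap]
  res0 <- moloc_region(g, e[e$gene == "GENE1", ], m[m$cpg == "cpg1", ])
  res1 <- moloc_region(g, e1, m[m$cpg == "cpg1", ])
  expect_equal(res1$ppa, res0$ppa, tolerance = 1e-10)
})

test_that("two-trait colocalization agrees with the marginalized engine", {
  sp <- scenario_spec(1, n_individuals = 20000, n_snps = 60, seed = 29)
  ch <- simulate_cohort(sp)
  g <- cohort_summary_stats(ch, "gwas")
  e <- cohort_summary_stats(ch, "eqtl")
  # methylation records replaced by pure noise
  m <- cohort_summary_stats(ch, "mqtl")
  set.seed(77)
  m$beta <- rnorm(nrow(m), 0, m$se)
  res3 <- moloc_region(g, e[e$gene == "GENE1", ], m)
  res2 <- moloc_region(g, e[e$gene == "GENE1", ], m = NULL)
  expect_lt(abs(summed_ppa(res3, c("G", "E")) -
                  summed_ppa(res2, c("G", "E"))), 0.05)
})

test_that("gene-centric CpG mapping applies the 1-Mb window", {
  lead <- 10e6
  cpgs <- c(cg1 = lead + 5e5, cg2 = lead + 1.5e6, cg3 = lead - 1e6)
  genes <- c(gA = lead - 3e5, gB = lead + 1e6, gC = lead + 2e6)
  combos <- map_cpg_to_genes(lead, cpgs, genes)
  # cg2 and gC excluded; inclusive at exactly 1 Mb
  expect_setequal(unique(combos$gene), c("gA", "gB"))
  expect_setequal(unique(combos$cpg), c("cg1", "cg3"))
  expect_equal(nrow(combos), 4)
  # full Cartesian count
  many <- map_cpg_to_genes(lead,
                           setNames(rep(lead, 4), paste0("c", 1:4)),
                           setNames(rep(lead, 3), paste0("g", 1:3)))
  expect_equal(nrow(many), 12)
  none <- map_cpg_to_genes(lead, c(c1 = lead + 2e6), genes)
  expect_equal(nrow(none), 0)
})
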