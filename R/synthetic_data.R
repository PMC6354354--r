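# Synthetic cohort generator: genotypes with LD, cis-eQTL / cis-mQTL effects,
# covariates and complex traits under five mechanistic scenarios.
#
# Scenario catalogue (the generative models every downstream stage is
# exercised against):
#   1  single-gene mediation: variant -> expression of one gene -> trait
#   2  multi-gene mediation: shared variant, >= 2 genes each affecting trait
#   3  co-regulation: shared variant drives several genes, only one causal
#   4  LD confounding: trait variant in LD with a distinct expression variant
#   5  horizontal pleiotropy: one variant hits expression and trait through
#      independent pathways (no mediation)

#' Specify a generative scenario for a synthetic cohort
#'
#' Collects every parameter of the generative model: genotype panel (sample
#' size, number of SNPs, allele frequencies, LD decay), cis-eQTL and cis-mQTL
#' effects, expression-to-trait mediation, direct (pleiotropic) variant
#' effects, covariate effects, residual noise and the seed. The object
#' validates the structural constraints of its scenario, e.g. scenario 1 must
#' have exactly one mediating gene and scenario 5 must combine a nonzero
#' direct effect with zero mediation.
#'
#' @param scenario_id integer in 1..5 selecting the mechanistic scenario.
#' @param n_individuals number of individuals.
#' @param n_snps number of variants in the simulated region.
#' @param maf per-SNP effect-allele frequencies, each in (0, 0.5]. Recycled.
#' @param ld_rho first-order autoregressive correlation between adjacent
#'   latent haplotype variables, in \[0, 1).
#' @param eqtl_effects named list, gene -> \code{list(snp, beta, tissue_scale)}
#'   where \code{tissue_scale} is a named numeric vector of per-tissue
#'   multipliers on \code{beta} (names define the tissue panel).
#' @param mqtl_effects named list, CpG -> \code{list(snp, beta)} (logit-scale
#'   effect on methylation).
#' @param mediation_effects named numeric vector, gene -> effect of one unit
#'   of expression on the trait.
#' @param pleiotropy_effect direct variant-on-trait effect per effect-allele
#'   copy. Attached to the first eQTL's SNP (scenario 5) or to the first SNP
#'   of \code{ld_pair} (scenario 4).
#' @param ld_pair scenario 4 only: \code{list(snps = c(i, j), r2 = target)}
#'   with two distinct SNP indices and the target dosage r-squared between
#'   them. The latent haplotype correlation over the gap is calibrated so the
#'   realised r-squared matches the target (tolerance about 0.05).
#' @param noise_sds list with elements \code{expression}, \code{methylation}
#'   (logit scale) and \code{trait}: residual standard deviations.
#' @param covariate_effects named numeric \code{c(age = ..., sex = ...)}:
#'   additive covariate effects on the trait.
#' @param age_range years; ages drawn uniformly over this interval.
#' @param log_trait logical: simulate the trait on a log scale and
#'   exponentiate (lognormal traits such as triglycerides).
#' @param trait_name name of the simulated complex trait.
#' @param seed integer seed; identical specs produce bit-identical cohorts.
#' @return an object of class \code{scenario_spec}.
#' @seealso [simulate_cohort()], [simulate_genotypes()]
#' @export
scenario_spec <- function(scenario_id,
                          n_individuals = 5000,
                          n_snps = 20,
                          maf = 0.3,
                          ld_rho = 0.5,
                          eqtl_effects = NULL,
                          mqtl_effects = NULL,
                          mediation_effects = NULL,
                          pleiotropy_effect = 0,
                          ld_pair = NULL,
                          noise_sds = list(expression = 1, methylation = 1,
                                           trait = 1),
                          covariate_effects = c(age = 0.05, sex = 0.1),
                          age_range = c(7, 11),
                          log_trait = FALSE,
                          trait_name = "trait",
                          seed = 1L) {
  scenario_id <- as.integer(scenario_id)
  if (!scenario_id %in% 1:5) stop("scenario_id must be one of 1..5")
  maf <- rep_len(maf, n_snps)

  mid <- max(1L, n_snps %/% 2L)
  if (is.null(eqtl_effects)) {
    eqtl_effects <- switch(scenario_id,
      `1` = list(GENE1 = list(snp = mid, beta = 0.4,
                              tissue_scale = c(whole_blood = 1))),
      `2` = list(GENE1 = list(snp = mid, beta = 0.4,
                              tissue_scale = c(whole_blood = 1)),
                 GENE2 = list(snp = mid, beta = 0.3,
                              tissue_scale = c(whole_blood = 1))),
      `3` = list(GENE1 = list(snp = mid, beta = 0.4,
                              tissue_scale = c(whole_blood = 1)),
                 GENE2 = list(snp = mid, beta = 0.4,
                              tissue_scale = c(whole_blood = 1))),
      `4` = list(GENE1 = list(snp = min(mid + 1L, n_snps), beta = 0.4,
                              tissue_scale = c(whole_blood = 1))),
      `5` = list(GENE1 = list(snp = mid, beta = 0.4,
                              tissue_scale = c(whole_blood = 1))))
  }
  if (is.null(mediation_effects)) {
    mediation_effects <- switch(scenario_id,
      `1` = c(GENE1 = 0.3),
      `2` = c(GENE1 = 0.3, GENE2 = 0.2),
      `3` = c(GENE1 = 0.3, GENE2 = 0),
      `4` = c(GENE1 = 0),
      `5` = c(GENE1 = 0))
  }
  if (scenario_id == 4L && is.null(ld_pair)) {
    ld_pair <- list(snps = c(mid, min(mid + 1L, n_snps)), r2 = 0.5)
  }
  if (scenario_id %in% c(4L, 5L) && pleiotropy_effect == 0) {
    pleiotropy_effect <- 0.3
  }
  if (is.null(mqtl_effects)) {
    first_snp <- eqtl_effects[[1]]$snp
    mqtl_effects <- list(cpg1 = list(snp = first_snp, beta = 0.5))
  }

  spec <- structure(list(
    scenario_id = scenario_id,
    n_individuals = as.integer(n_individuals),
    n_snps = as.integer(n_snps),
    maf = maf,
    ld_rho = ld_rho,
    eqtl_effects = eqtl_effects,
    mqtl_effects = mqtl_effects,
    mediation_effects = mediation_effects,
    pleiotropy_effect = pleiotropy_effect,
    ld_pair = ld_pair,
    noise_sds = noise_sds,
    covariate_effects = covariate_effects,
    age_range = age_range,
    log_trait = log_trait,
    trait_name = trait_name,
    seed = as.integer(seed)
  ), class = "scenario_spec")
  validate_scenario_spec(spec)
  spec
}

validate_scenario_spec <- function(spec) {
  with(spec, {
    if (n_individuals < 2) stop("n_individuals must be >= 2")
    if (any(maf <= 0 | maf > 0.5)) stop("all MAFs must lie in (0, 0.5]")
    if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
    sds <- unlist(noise_sds)
    if (any(sds <= 0)) stop("all noise SDs must be positive")
    snps <- vapply(eqtl_effects, function(e) e$snp, numeric(1))
    if (any(snps < 1 | snps > n_snps))
      stop("eQTL causal SNP index out of range")
    msnps <- vapply(mqtl_effects, function(e) e$snp, numeric(1))
    if (any(msnps < 1 | msnps > n_snps))
      stop("mQTL causal SNP index out of range")
    med <- mediation_effects[names(eqtl_effects)]
    n_nonzero <- sum(med != 0, na.rm = TRUE)
    if (scenario_id == 1L && n_nonzero != 1L)
      stop("scenario 1 requires exactly one gene with nonzero mediation")
    if (scenario_id == 2L && n_nonzero < 2L)
      stop("scenario 2 requires >= 2 genes with nonzero mediation")
    if (scenario_id == 3L) {
      if (length(eqtl_effects) < 2L || length(unique(snps)) != 1L)
        stop("scenario 3 requires co-regulated genes sharing one causal SNP")
      if (n_nonzero != 1L)
        stop("scenario 3 requires exactly one nonzero mediation effect")
    }
    if (scenario_id == 4L) {
      if (is.null(ld_pair) || length(unique(ld_pair$snps)) != 2L)
        stop("scenario 4 requires two distinct causal SNP indices in ld_pair")
      if (any(ld_pair$snps < 1 | ld_pair$snps > n_snps))
        stop("ld_pair SNP indices out of range")
    }
    if (scenario_id == 5L) {
      if (pleiotropy_effect == 0)
        stop("scenario 5 requires a nonzero pleiotropy_effect")
      if (n_nonzero != 0L)
        stop("scenario 5 requires zero mediation via the co-simulated gene")
    }
  })
  invisible(spec)
}

# Bivariate standard normal orthant probability P(Z1 < t1, Z2 < t2 | rho),
# by 1-D quadrature; used to calibrate latent haplotype correlations.
bvn_lower <- function(t1, t2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(t1) * stats::pnorm(t2))
  f <- function(x) {
    stats::dnorm(x) * stats::pnorm((t2 - rho * x) / sqrt(1 - rho^2))
  }
  stats::integrate(f, -Inf, t1, rel.tol = 1e-10)$value
}

# Dosage correlation implied by latent correlation `rho` for threshold MAFs
# p1, p2 (alleles are thresholded latent Gaussians; summing two independent
# haplotypes leaves the correlation unchanged).
latent_to_dosage_cor <- function(rho, p1, p2) {
  t1 <- stats::qnorm(p1); t2 <- stats::qnorm(p2)
  p11 <- bvn_lower(t1, t2, rho)
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Latent correlation needed to hit a target dosage r^2 (signed r > 0).
calibrate_latent_rho <- function(target_r2, p1, p2) {
  target_r <- sqrt(target_r2)
  if (target_r2 <= 0) return(0)
  f <- function(rho) latent_to_dosage_cor(rho, p1, p2) - target_r
  if (f(1 - 1e-9) < 0) return(1 - 1e-9)  # target unreachable; saturate
  stats::uniroot(f, c(0, 1 - 1e-9), tol = 1e-8)$root
}

# One haplotype panel: latent Gaussian AR process with per-gap correlations
# `rho_gaps` (length m - 1), thresholded at qnorm(maf).
simulate_haplotypes <- function(n, maf, rho_gaps) {
  m <- length(maf)
  z <- matrix(0, n, m)
  z[, 1] <- stats::rnorm(n)
  if (m > 1) for (k in 2:m) {
    r <- rho_gaps[k - 1]
    z[, k] <- r * z[, k - 1] + sqrt(1 - r^2) * stats::rnorm(n)
  }
  sweep(z, 2, stats::qnorm(maf), `<`) * 1L
}

#' Simulate a dosage matrix with autoregressive linkage disequilibrium
#'
#' Dosages arise as the sum of two independent haplotypes. Each haplotype is
#' a latent Gaussian first-order autoregressive process thresholded at the
#' allele-frequency quantile, so the correlation between adjacent SNPs decays
#' geometrically with distance (\code{ld_rho^gap} on the latent scale).
#'
#' @param n number of individuals (>= 2).
#' @param maf effect-allele frequencies in (0, 0.5], one per SNP.
#' @param ld_rho adjacent-SNP latent correlation in \[0, 1).
#' @param seed integer seed.
#' @param rho_gaps optional vector of per-gap latent correlations overriding
#'   the constant \code{ld_rho} (used to hit a target r-squared for one pair).
#' @return an \code{n x length(maf)} integer matrix with entries in
#'   \{0, 1, 2\} counting effect-allele copies.
#' @examples
#' g <- simulate_genotypes(100, maf = rep(0.3, 5), ld_rho = 0.6, seed = 1)
#' colMeans(g) / 2  # close to 0.3
#' @export
simulate_genotypes <- function(n, maf, ld_rho, seed, rho_gaps = NULL) {
  if (n < 2) stop("n must be >= 2")
  if (any(maf <= 0 | maf > 0.5)) stop("all MAFs must lie in (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  m <- length(maf)
  if (is.null(rho_gaps)) rho_gaps <- rep(ld_rho, max(m - 1L, 0L))
  with_seed(seed, {
    h1 <- simulate_haplotypes(n, maf, rho_gaps)
    h2 <- simulate_haplotypes(n, maf, rho_gaps)
    g <- h1 + h2
    storage.mode(g) <- "integer"
    colnames(g) <- sprintf("snp_%02d", seq_len(m))
    g
  })
}

# Variant metadata for a simulated region: one chromosome, evenly spaced
# positions, alternating non-palindromic allele pairs.
variant_metadata <- function(n_snps, maf, chrom = "1", start = 1e6L,
                             spacing = 1e4L) {
  pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2,
                  byrow = TRUE)
  idx <- ((seq_len(n_snps) - 1L) %% 4L) + 1L
  data.frame(
    variant_id = sprintf("snp_%02d", seq_len(n_snps)),
    chrom = chrom,
    pos = start + (seq_len(n_snps) - 1L) * spacing,
    effect_allele = pairs[idx, 1],
    other_allele = pairs[idx, 2],
    maf = maf,
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort under a mechanistic scenario
#'
#' Generates genotypes, covariates (age, sex), per-tissue gene expression,
#' CpG methylation and the complex trait according to the structural model of
#' the scenario in \code{spec}:
#' \itemize{
#'   \item expression\code{[, g]} = eQTL beta (x tissue scale) * dosage +
#'     Gaussian noise;
#'   \item methylation is generated on the logit scale (mQTL beta * dosage +
#'     noise) and squashed into (0, 1) with the logistic function, matching
#'     array beta-values;
#'   \item trait = sum over genes of mediation * expression + direct variant
#'     effect + age and sex effects + Gaussian noise. In scenario 4 the trait
#'     is driven directly by the first SNP of \code{ld_pair} while the second
#'     drives expression; in scenario 5 the direct effect shares the
#'     expression SNP (horizontal pleiotropy).
#' }
#'
#' @param spec a [scenario_spec()].
#' @return an object of class \code{cohort}: list with \code{dosages},
#'   \code{age}, \code{sex}, \code{expression} (reference-tissue matrix),
#'   \code{tissue_expression} (named list of matrices, one per tissue),
#'   \code{methylation}, \code{traits} (named list of numeric vectors),
#'   \code{variant_meta}, \code{gene_meta}, \code{cpg_meta} and \code{truth}
#'   (the generating spec, round-tripped verbatim).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  validate_scenario_spec(spec)
  n <- spec$n_individuals
  m <- spec$n_snps
  seeds <- split_seed(spec$seed, 6L)

  rho_gaps <- rep(spec$ld_rho, max(m - 1L, 0L))
  if (!is.null(spec$ld_pair)) {
    i <- min(spec$ld_pair$snps); j <- max(spec$ld_pair$snps)
    lat <- calibrate_latent_rho(spec$ld_pair$r2,
                                spec$maf[i], spec$maf[j])
    # spread the required latent correlation across the gaps i..j
    gap_rho <- lat^(1 / (j - i))
    rho_gaps[i:(j - 1L)] <- gap_rho
  }
  dosages <- simulate_genotypes(n, spec$maf, spec$ld_rho, seeds[1],
                                rho_gaps = rho_gaps)

  age <- with_seed(seeds[2], stats::runif(n, spec$age_range[1],
                                          spec$age_range[2]))
  sex <- with_seed(seeds[3], stats::rbinom(n, 1L, 0.5))

  genes <- names(spec$eqtl_effects)
  tissues <- unique(unlist(lapply(spec$eqtl_effects,
                                  function(e) names(e$tissue_scale))))
  if (is.null(tissues)) tissues <- "whole_blood"
  expr_sd <- rep_len(unlist(spec$noise_sds$expression), length(genes))
  tissue_expression <- with_seed(seeds[4], {
    out <- lapply(tissues, function(tis) {
      em <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
      for (k in seq_along(genes)) {
        e <- spec$eqtl_effects[[k]]
        scale_t <- e$tissue_scale[tis]
        if (is.na(scale_t)) scale_t <- 1
        em[, k] <- e$beta * scale_t * dosages[, e$snp] +
          stats::rnorm(n, 0, expr_sd[k])
      }
      em
    })
    names(out) <- tissues
    out
  })
  expression <- tissue_expression[[1]]

  cpgs <- names(spec$mqtl_effects)
  meth_sd <- rep_len(unlist(spec$noise_sds$methylation), length(cpgs))
  methylation <- with_seed(seeds[5], {
    mm <- matrix(0, n, length(cpgs), dimnames = list(NULL, cpgs))
    for (k in seq_along(cpgs)) {
      e <- spec$mqtl_effects[[k]]
      latent <- e$beta * dosages[, e$snp] + stats::rnorm(n, 0, meth_sd[k])
      mm[, k] <- stats::plogis(latent)
    }
    mm
  })

  med <- spec$mediation_effects
  trait <- with_seed(seeds[6], {
    y <- stats::rnorm(n, 0, rep_len(unlist(spec$noise_sds$trait), 1L))
    for (g in names(med)) {
      if (!is.null(expression) && g %in% colnames(expression) && med[g] != 0)
        y <- y + med[g] * expression[, g]
    }
    if (spec$pleiotropy_effect != 0) {
      direct_snp <- if (spec$scenario_id == 4L) spec$ld_pair$snps[1]
                    else spec$eqtl_effects[[1]]$snp
      y <- y + spec$pleiotropy_effect * dosages[, direct_snp]
    }
    y <- y + spec$covariate_effects["age"] * age +
      spec$covariate_effects["sex"] * sex
    if (isTRUE(spec$log_trait)) y <- exp(y) else y
  })

  vmeta <- variant_metadata(m, spec$maf)
  gene_meta <- data.frame(
    gene = genes,
    tss = vmeta$pos[vapply(spec$eqtl_effects, function(e) e$snp,
                           numeric(1))],
    stringsAsFactors = FALSE
  )
  cpg_meta <- data.frame(
    cpg = cpgs,
    pos = vmeta$pos[vapply(spec$mqtl_effects, function(e) e$snp,
                           numeric(1))],
    stringsAsFactors = FALSE
  )

  traits <- stats::setNames(list(as.numeric(trait)), spec$trait_name)
  structure(list(
    dosages = dosages, age = age, sex = as.integer(sex),
    expression = expression, tissue_expression = tissue_expression,
    methylation = methylation, traits = traits,
    variant_meta = vmeta, gene_meta = gene_meta, cpg_meta = cpg_meta,
    truth = spec
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d individuals, %d SNPs, scenario %d\n",
              nrow(x$dosages), ncol(x$dosages), x$truth$scenario_id))
  cat(sprintf("  genes: %s | CpGs: %s | traits: %s\n",
              paste(colnames(x$expression), collapse = ", "),
              paste(colnames(x$methylation), collapse = ", "),
              paste(names(x$traits), collapse = ", ")))
  invisible(x)
}

#' Body mass index
#'
#' @param weight_kg weight in kilograms (> 0).
#' @param height_m height in metres (> 0).
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(50, 1.25)  # 32
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0))
    stop("weight and height must be positive")
  weight_kg / height_m^2
}

#' LDL cholesterol by the Friedewald equation
#'
#' LDL = TC - HDL - TG/2.2 in mmol/L (divisor 5.0 for mg/dL). The formula is
#' invalid at high triglyceride levels; such inputs yield a flagged missing
#' value (\code{NA}) rather than an error.
#'
#' @param tc total cholesterol.
#' @param hdl HDL cholesterol.
#' @param tg triglycerides (same units as \code{tc}).
#' @param tg_max validity bound on triglycerides; default 4.52 mmol/L
#'   (equivalently 400 mg/dL).
#' @param divisor 2.2 for mmol/L (default), 5.0 for mg/dL.
#' @return estimated LDL cholesterol; \code{NA} where \code{tg > tg_max},
#'   with the offending indices in attribute \code{"flagged"}.
#' @examples
#' compute_friedewald_ldl(5.0, 1.0, 2.2)  # 3.0
#' @export
compute_friedewald_ldl <- function(tc, hdl, tg, tg_max = 4.52,
                                   divisor = 2.2) {
  if (any(tc < 0, na.rm = TRUE) || any(hdl < 0, na.rm = TRUE) ||
      any(tg < 0, na.rm = TRUE))
    stop("lipid measurements must be non-negative")
  ldl <- tc - hdl - tg / divisor
  bad <- which(tg > tg_max)
  ldl[bad] <- NA_real_
  attr(ldl, "flagged") <- bad
  ldl
}

#' Write a cohort to plain-text files
#'
#' Writes \code{dosages.tsv} (individuals x variants), \code{phenotypes.tsv}
#' (age, sex, expression, methylation, traits) and \code{variants.tsv}
#' (chrom, 1-based pos, effect/other allele, MAF), plus optionally a minimal
#' VCF with a DS (dosage) FORMAT field.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @param vcf also write \code{dosages.vcf}? Default \code{FALSE}.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, vcf = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("dosages.tsv", "phenotypes.tsv", "variants.tsv"))
  utils::write.table(cohort$dosages, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pheno <- data.frame(age = cohort$age, sex = cohort$sex,
                      cohort$expression, cohort$methylation,
                      check.names = FALSE)
  for (tr in names(cohort$traits)) pheno[[tr]] <- cohort$traits[[tr]]
  utils::write.table(pheno, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$variant_meta, paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (vcf) {
    vp <- file.path(dir, "dosages.vcf")
    con <- file(vp, "w")
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT",
                         sprintf("ind%04d", seq_len(nrow(cohort$dosages)))),
                       collapse = "\t")), con)
    vm <- cohort$variant_meta
    for (k in seq_len(nrow(vm))) {
      writeLines(paste(c(vm$chrom[k], vm$pos[k], vm$variant_id[k],
                         vm$other_allele[k], vm$effect_allele[k], ".",
                         "PASS", ".", "DS", cohort$dosages[, k]),
                       collapse = "\t"), con)
    }
    close(con)
    paths <- c(paths, vp)
  }
  invisible(paths)
}

#' Read / write a scenario specification as a YAML config
#'
#' Field names in the file match the arguments of [scenario_spec()] exactly.
#'
#' @param spec a \code{scenario_spec}.
#' @param path file path.
#' @return \code{write_scenario_spec} returns the path invisibly;
#'   \code{read_scenario_spec} returns a validated \code{scenario_spec}.
#' @export
write_scenario_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  x <- unclass(spec)
  # yaml drops names from named atomic vectors; store them as maps
  x$mediation_effects <- as.list(x$mediation_effects)
  x$covariate_effects <- as.list(x$covariate_effects)
  x$eqtl_effects <- lapply(x$eqtl_effects, function(e) {
    e$tissue_scale <- as.list(e$tissue_scale); e
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_spec
#' @export
read_scenario_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$covariate_effects <- unlist(x$covariate_effects)
  x$mediation_effects <- unlist(x$mediation_effects)
  x$eqtl_effects <- lapply(x$eqtl_effects, function(e) {
    e$tissue_scale <- unlist(e$tissue_scale); e
  })
  do.call(scenario_spec, x)
}
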