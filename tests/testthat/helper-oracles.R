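# Test helpers: summary-record builders and independent brute-force oracles.
# The oracles deliberately share no code with the package internals: plain
# density evaluations and exhaustive loops over assignments.

make_record <- function(variant_id = "rs1", chrom = "1", pos = 1e6,
                        effect_allele = "A", other_allele = "G", eaf = 0.3,
                        beta = 0.1, se = 0.02, p = NULL, n = 1000,
                        trait = "trait", info = NA_real_) {
  if (is.null(p)) p <- 2 * pnorm(abs(beta / se), lower.tail = FALSE)
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, p = p, n = n, trait = trait,
             info = info, stringsAsFactors = FALSE)
}

lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log density of a zero-mean multivariate normal, by direct factorization
ldmvn <- function(z, S) {
  ch <- chol(S)
  -0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, z, transpose = TRUE)^2))
}

# Exhaustive fine-mapping oracle: scores every causal configuration by
# evaluating both multivariate normal densities outright.
oracle_finemap <- function(z, R, n, k_max, prior_sd, ridge = 1e-6) {
  m <- length(z)
  S0 <- R + diag(ridge, m)
  subsets <- list(integer(0))
  for (k in seq_len(min(k_max, m)))
    subsets <- c(subsets, combn(m, k, simplify = FALSE))
  log_bf <- vapply(subsets, function(s) {
    if (length(s) == 0L) return(0)
    S1 <- S0 + n * prior_sd^2 *
      R[, s, drop = FALSE] %*% R[s, , drop = FALSE]
    ldmvn(z, S1) - ldmvn(z, S0)
  }, numeric(1))
  sizes <- lengths(subsets)
  log_prior <- sizes * log(1 / m) + (m - sizes) * log(1 - 1 / m)
  lp <- log_prior + log_bf
  post <- exp(lp - lse(lp))
  pip <- numeric(m)
  for (i in seq_along(subsets))
    pip[subsets[[i]]] <- pip[subsets[[i]]] + post[i]
  list(subsets = subsets, log_bf = log_bf, posterior = post, pip = pip)
}

# Colocalization evidence oracle: directly sums over every assignment of
# distinct SNPs to the causal groups.
oracle_config_evidence <- function(groups, log_abf, priors) {
  g <- length(groups)
  if (g == 0L) return(0)
  m <- nrow(log_abf)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(m)), g)))
  keep <- apply(grid, 1, function(r) !anyDuplicated(r))
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L) return(-Inf)
  logs <- apply(grid, 1, function(r)
    sum(vapply(seq_len(g), function(h)
      log(priors[length(groups[[h]])]) +
        sum(log_abf[r[h], groups[[h]]]), numeric(1))))
  lse(logs)
}

oracle_moloc_ppa <- function(log_abf, priors) {
  configs <- enumerate_configurations(ncol(log_abf))
  ev <- vapply(configs, function(cf)
    oracle_config_evidence(cf$groups, log_abf, priors), numeric(1))
  ppa <- exp(ev - lse(ev))
  names(ppa) <- vapply(configs, `[[`, character(1), "label")
  ppa
}

# Quick scenario-1 cohort with sensible small defaults for module tests
small_cohort <- function(n = 2000, n_snps = 10, seed = 1, ...) {
  simulate_cohort(scenario_spec(1, n_individuals = n, n_snps = n_snps,
                                seed = seed, ...))
}
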