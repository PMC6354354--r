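# Bayesian multiple-trait colocalization: per-SNP Wakefield approximate
# Bayes factors for each trait, enumeration of all sharing configurations
# (15 for three traits), per-SNP priors by sharing depth, posterior
# probabilities of association (PPA) and summed-PPA decision rules.
#
# A configuration assigns a subset of the traits to causal groups; traits in
# one group share a single causal SNP, different groups occupy distinct
# SNPs, and omitted traits have no association in the region. The evidence
# for a configuration with groups D_1..D_g is
#   sum over assignments of distinct SNPs (j_1..j_g) of
#     prod_h [ p_{|D_h|} * prod_{t in D_h} ABF_t(j_h) ]
# with per-SNP priors p_1, p_2, p_3 for groups shared by one, two or three
# traits. The null term is 1. All sums run in log space; the
# distinct-assignment constraint is resolved by Moebius inversion over set
# partitions of the groups, which keeps the cost linear in the number of
# SNPs.

#' Wakefield log approximate Bayes factor
#'
#' Closed-form evidence for a SNP's association from its estimate and
#' standard error under a Gaussian effect prior:
#' \code{ABF = sqrt(1 - r) * exp(r * z^2 / 2)} with \code{z = beta/se},
#' \code{r = W / (V + W)}, \code{V = se^2} and \code{W = prior_sd^2}.
#'
#' @param beta,se effect estimate and standard error (vectorized; se > 0).
#' @param prior_sd prior standard deviation of the true effect
#'   (default 0.15, the convention for continuous traits).
#' @return log approximate Bayes factor(s), natural log.
#' @export
wakefield_log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0, na.rm = TRUE)) stop("standard errors must be positive")
  if (prior_sd <= 0) stop("prior_sd must be positive")
  V <- se^2
  r <- prior_sd^2 / (V + prior_sd^2)
  z <- beta / se
  0.5 * log1p(-r) + r * z^2 / 2
}

# All set partitions of a character vector, as lists of groups.
set_partitions <- function(items) {
  n <- length(items)
  if (n == 0L) return(list(list()))
  if (n == 1L) return(list(list(items)))
  rest <- set_partitions(items[-1])
  out <- list()
  for (p in rest) {
    # put items[1] into each existing block, or alone
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(items[1], q[[b]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(items[1]), p)
  }
  out
}

config_label <- function(groups, trait_order) {
  if (length(groups) == 0L) return("null")
  labs <- vapply(groups, function(g)
    paste(trait_order[sort(match(g, trait_order))], collapse = ""),
    character(1))
  paste(sort(labs), collapse = ".")
}

#' Enumerate trait-sharing configurations
#'
#' All set partitions of all subsets of the trait set (including the empty
#' configuration, labelled \code{"null"}): 2 configurations for one trait,
#' 5 for two, 15 for three, 52 for four. Labels are dot-separated groups
#' with traits in the canonical order of \code{labels} (e.g. \code{"GE.M"}
#' means G and E share a causal SNP and M has its own).
#'
#' @param n_traits number of traits (1..4).
#' @param labels trait labels in canonical order (default G, E, M, T4:
#'   GWAS trait, expression, methylation).
#' @return list of configurations, each a list with \code{label} and
#'   \code{groups} (list of character vectors); deterministic ordering by
#'   number of traits involved, then number of groups, then label.
#' @examples
#' length(enumerate_configurations(3))  # 15
#' @export
enumerate_configurations <- function(n_traits,
                                     labels = c("G", "E", "M", "T4")) {
  if (n_traits < 1 || n_traits > 4) stop("n_traits must lie in 1..4")
  traits <- labels[seq_len(n_traits)]
  out <- list(list(label = "null", groups = list()))
  subsets <- unlist(lapply(seq_len(n_traits), function(k)
    utils::combn(traits, k, simplify = FALSE)), recursive = FALSE)
  for (s in subsets) {
    for (p in set_partitions(s)) {
      out[[length(out) + 1L]] <- list(label = config_label(p, traits),
                                      groups = p)
    }
  }
  key <- vapply(out, function(cf)
    sprintf("%d-%d-%s", sum(lengths(cf$groups)), length(cf$groups),
            cf$label), character(1))
  out[order(key)]
}

# Moebius coefficient of a partition of the group indices:
# prod over blocks of (-1)^(|B|-1) * (|B|-1)!
partition_moebius <- function(p) {
  prod(vapply(p, function(b) (-1)^(length(b) - 1) *
                factorial(length(b) - 1), numeric(1)))
}

# log evidence of one configuration given the m x n_traits log-ABF matrix.
# priors[k] = per-SNP prior for a group of k traits.
config_log_evidence <- function(groups, log_abf, priors) {
  if (length(groups) == 0L) return(0)  # null term = 1
  m <- nrow(log_abf)
  if (length(groups) > m) return(-Inf)  # not enough distinct SNPs
  # per-group per-SNP log scores
  S <- lapply(groups, function(g)
    log(priors[length(g)]) +
      rowSums(log_abf[, g, drop = FALSE]))
  idx <- seq_along(groups)
  terms_log <- numeric(0)
  terms_sign <- numeric(0)
  for (p in set_partitions(idx)) {
    mu <- partition_moebius(p)
    lp <- sum(vapply(p, function(b)
      logsumexp(Reduce(`+`, S[b])), numeric(1)))
    terms_log <- c(terms_log, lp)
    terms_sign <- c(terms_sign, mu)
  }
  res <- logsumexp_signed(terms_log, terms_sign)
  if (res$sign <= 0) -Inf else res$log
}

# Align records of `other` onto `ref` by variant_id and effect allele.
# Returns `other` restricted/reordered to the shared ids, betas flipped
# where the alleles are swapped; variants with irreconcilable alleles are
# dropped.
align_records <- function(ref, other) {
  ids <- intersect(ref$variant_id, other$variant_id)
  ref <- ref[match(ids, ref$variant_id), , drop = FALSE]
  oth <- other[match(ids, other$variant_id), , drop = FALSE]
  same <- toupper(oth$effect_allele) == toupper(ref$effect_allele) &
    toupper(oth$other_allele) == toupper(ref$other_allele)
  swap <- toupper(oth$effect_allele) == toupper(ref$other_allele) &
    toupper(oth$other_allele) == toupper(ref$effect_allele)
  oth$beta[swap] <- -oth$beta[swap]
  oth$eaf[swap] <- 1 - oth$eaf[swap]
  oth$effect_allele[swap] <- ref$effect_allele[swap]
  oth$other_allele[swap] <- ref$other_allele[swap]
  keep <- same | swap
  oth[keep, , drop = FALSE]
}

#' Multiple-trait colocalization of a region
#'
#' Takes per-SNP summary statistics for a GWAS trait (G), gene expression
#' (E) and optionally DNA methylation (M) over one region, intersects the
#' datasets on variants passing the MAF filter, computes Wakefield log ABFs
#' per SNP and trait, and evaluates the posterior probability of every
#' sharing configuration (15 for three traits, 5 for two).
#'
#' @param g,e,m summary-statistics data frames (one trait each) sharing a
#'   variant namespace; \code{m = NULL} runs the two-trait analysis with the
#'   same engine.
#' @param priors per-SNP prior probabilities for a causal SNP private to one
#'   trait, shared by two, shared by three: default
#'   \code{c(1e-4, 1e-6, 1e-7)}, the developers' recommendation.
#' @param min_snps minimum number of common SNPs after filtering
#'   (default 50); regions below it return a structured skip, not an error.
#' @param maf_min per-dataset minor-allele-frequency filter, inclusive at
#'   the bound (default 0.05).
#' @param prior_sd Wakefield effect prior SD, scalar or one per trait
#'   (default 0.15).
#' @param ppa_threshold decision threshold on summed PPAs (default 0.8).
#' @return an object of class \code{moloc_result}: list with \code{status}
#'   (\code{"ok"} or \code{"insufficient_snps"}), \code{ppa} (named vector
#'   over configuration labels, summing to 1), \code{n_snps_used},
#'   \code{summed_ge} (total PPA of configurations where G and E share a
#'   SNP), \code{gem} (PPA of the all-share configuration),
#'   \code{decision_ge}, \code{decision_gem} (at the 0.8 rule) and
#'   \code{configurations}.
#' @export
moloc_region <- function(g, e, m = NULL, priors = c(1e-4, 1e-6, 1e-7),
                         min_snps = 50, maf_min = 0.05, prior_sd = 0.15,
                         ppa_threshold = 0.8) {
  traits <- if (is.null(m)) list(G = g, E = e) else list(G = g, E = e, M = m)
  if (any(priors <= 0) || any(priors >= 1))
    stop("priors must lie in (0, 1)")
  maf_pass <- function(rec) {
    maf <- pmin(rec$eaf, 1 - rec$eaf)
    rec[!is.na(maf) & maf >= maf_min, , drop = FALSE]
  }
  traits <- lapply(traits, maf_pass)
  ref <- traits[[1]]
  for (k in seq_along(traits)[-1]) {
    traits[[k]] <- align_records(ref, traits[[k]])
    ids <- traits[[k]]$variant_id
    traits <- lapply(traits, function(tr)
      tr[match(intersect(ids, tr$variant_id), tr$variant_id), ,
         drop = FALSE])
    ref <- traits[[1]]
  }
  ids <- traits[[1]]$variant_id
  n_common <- length(ids)
  if (n_common < min_snps) {
    return(structure(list(status = "insufficient_snps",
                          reason = sprintf("insufficient SNPs (<%d)",
                                           min_snps),
                          n_snps_used = n_common, ppa = NULL,
                          summed_ge = NA_real_, gem = NA_real_,
                          decision_ge = NA, decision_gem = NA,
                          configurations = NULL),
                     class = "moloc_result"))
  }
  prior_sd <- rep_len(prior_sd, length(traits))
  log_abf <- do.call(cbind, lapply(seq_along(traits), function(k)
    wakefield_log_abf(traits[[k]]$beta, traits[[k]]$se, prior_sd[k])))
  colnames(log_abf) <- names(traits)

  configs <- enumerate_configurations(length(traits))
  log_ev <- vapply(configs, function(cf)
    config_log_evidence(cf$groups, log_abf, priors), numeric(1))
  log_ppa <- log_ev - logsumexp(log_ev)
  ppa <- stats::setNames(exp(log_ppa),
                         vapply(configs, `[[`, character(1), "label"))

  res <- structure(list(status = "ok", ppa = ppa, n_snps_used = n_common,
                        configurations = configs,
                        summed_ge = NA_real_, gem = NA_real_,
                        decision_ge = NA, decision_gem = NA),
                   class = "moloc_result")
  res$summed_ge <- summed_ppa(res, c("G", "E"))
  res$gem <- if (length(traits) == 3L) unname(ppa["GEM"]) else NA_real_
  res$decision_ge <- isTRUE(res$summed_ge >= ppa_threshold)
  res$decision_gem <- isTRUE(res$gem >= ppa_threshold)
  res
}

#' Summed posterior probability of colocalization for a trait subset
#'
#' Sums the PPAs of all configurations containing a causal group that
#' includes every trait in \code{subset} (e.g. \code{c("G","E")} sums the
#' GE, GE.M and GEM configurations -- every way G and E can share a SNP).
#'
#' @param result an ok-status [moloc_region()] result.
#' @param subset nonempty character vector of trait labels.
#' @return the summed PPA.
#' @export
summed_ppa <- function(result, subset) {
  stopifnot(inherits(result, "moloc_result"),
            identical(result$status, "ok"))
  if (length(subset) == 0L) stop("subset must be nonempty")
  known <- unique(unlist(lapply(result$configurations,
                                function(cf) unlist(cf$groups))))
  if (!all(subset %in% known))
    stop("unknown trait label(s): ",
         paste(setdiff(subset, known), collapse = ", "))
  sel <- vapply(result$configurations, function(cf)
    any(vapply(cf$groups, function(grp) all(subset %in% grp), logical(1))),
    logical(1))
  sum(result$ppa[sel])
}

#' @export
print.moloc_result <- function(x, ...) {
  if (x$status != "ok") {
    cat("moloc: region skipped --", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("moloc: %d common SNPs, %d configurations\n", x$n_snps_used,
              length(x$ppa)))
  top <- sort(x$ppa, decreasing = TRUE)[1:5]
  print(round(top, 4))
  cat(sprintf("summed PPA(G,E) = %.3f%s\n", x$summed_ge,
              if (isTRUE(x$decision_ge)) "  [colocalized]" else ""))
  if (!is.na(x$gem))
    cat(sprintf("PPA(GEM) = %.3f%s\n", x$gem,
                if (isTRUE(x$decision_gem)) "  [all three share]" else ""))
  invisible(x)
}

#' Gene x CpG combinations around a lead SNP
#'
#' Gene-centric scan support: all (gene, CpG) pairs where both the gene TSS
#' and the CpG lie within \code{window} of the lead SNP (positions on one
#' chromosome).
#'
#' @param lead_pos lead SNP position (bp).
#' @param cpgs named numeric vector of CpG positions.
#' @param genes named numeric vector of gene TSS positions.
#' @param window half-width in bp (default 1 Mb, inclusive).
#' @return data frame with columns \code{gene}, \code{cpg}, ordered by gene
#'   then CpG name.
#' @export
map_cpg_to_genes <- function(lead_pos, cpgs, genes, window = 1e6) {
  g_in <- names(genes)[abs(genes - lead_pos) <= window]
  c_in <- names(cpgs)[abs(cpgs - lead_pos) <= window]
  if (length(g_in) == 0L || length(c_in) == 0L)
    return(data.frame(gene = character(0), cpg = character(0)))
  out <- expand.grid(cpg = sort(c_in), gene = sort(g_in),
                     stringsAsFactors = FALSE)[, c("gene", "cpg")]
  out <- out[order(out$gene, out$cpg), , drop = FALSE]
  rownames(out) <- NULL
  out
}
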