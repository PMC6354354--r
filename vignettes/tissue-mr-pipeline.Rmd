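---
title: "Methods: from eQTL association to tissue-specific MR and multiple-trait colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from eQTL association to tissue-specific MR and multiple-trait colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuemr)
```

# The problem

A large fraction of variants detected by genome-wide association studies
(GWAS) fall in non-coding regions, and the working hypothesis is that many
of them act on complex traits by changing the regulation of nearby genes.
`tissuemr` implements a triage pipeline for such loci: given a variant
associated with both the expression of a nearby gene (a *cis*-eQTL) and a
complex trait, it asks which of five mechanisms best explains the signal:

1. **Single-gene mediation** — the variant changes the expression of one
   gene, which changes the trait.
2. **Multi-gene mediation** — the variant drives several co-regulated
   genes, more than one of which affects the trait.
3. **Co-regulation** — several genes share the variant, but only one is
   causal for the trait.
4. **LD confounding** — the trait variant is merely in linkage
   disequilibrium (LD) with a distinct expression variant.
5. **Horizontal pleiotropy** — one variant affects expression and trait
   through independent pathways.

The pipeline chains four statistical stages — an eQTL-wide association
study (eQTLWAS), Bayesian fine-mapping, single-instrument Mendelian
randomization (MR) with a directionality test, and Bayesian multiple-trait
colocalization of trait, expression and DNA methylation — and ships a
synthetic-data generator that simulates cohorts under each of the five
mechanisms so every stage can be calibrated end to end.

# Stage models

## eQTL-wide association study

Phenotypes are cleaned by removing values beyond 4 standard deviations of
the mean (mean and SD computed once, on the full non-missing sample; the
scan is therefore a single pass and idempotent; a constant phenotype is
returned untouched rather than emptied). Optionally a trait is
log-transformed first — which traits deserve the transform is
data-dependent, so it is a per-trait switch (`log_flags`) rather than a
fixed list. Variants are kept when the imputation info score is at least
0.8 (missing scores pass, but are counted) and the minor allele frequency
is strictly above 0.01.

Each variant is then tested by ordinary least squares of the phenotype on
additive dosage with age and sex as covariates. P-values use the t
reference with residual degrees of freedom rather than a normal
approximation, matching standard regression output. For complete-data
designs the covariates are projected out once (Frisch–Waugh–Lovell), which
makes a 500-variant scan one matrix product; the estimates are identical
to per-variant `lm` fits, and the tests verify this equality to 1e-10.
The family-wise gate is Bonferroni: `alpha / (instruments x traits)`.
Lead SNPs are obtained by greedy clumping (smallest p first, ties broken
lexicographically by variant id, a 1-Mb exclusion radius).

## Fine-mapping by exhaustive enumeration

For a region around a lead SNP, let `z` be the per-SNP z-scores and `R`
the LD correlation matrix. Under the null `z ~ N(0, R)`; a configuration
`S` of causal SNPs with independent Gaussian effect priors of standard
deviation `prior_sd` on the standardized scale implies
`z ~ N(0, R + n * prior_sd^2 * R[,S] R[S,])`. The Bayes factor of `S` is
the ratio of the two densities at the observed `z`. Every configuration of
at most `k_max` variants (default 5) is scored — exhaustive enumeration is
exact at this scale and serves as its own guarantee, so no stochastic
search is involved; this is a deliberate design decision, not an
emulation of any particular search tool. Per-SNP posterior inclusion
probabilities (PIPs) are the posterior mass of configurations containing
the SNP.

Numerical choices: a ridge of 1e-6 is added to `R`'s diagonal before
factorization; configuration scores reuse one Cholesky factor of the null
covariance through low-rank (Woodbury/determinant-lemma) updates, so the
per-configuration cost is cubic in `|S|`, not in the region size;
normalization happens in log space via log-sum-exp. The configuration
prior is independent per-SNP inclusion with probability `1/m` truncated at
`k_max` (a uniform-on-size alternative is available). The enumeration is
capped (default 2e6 configurations) and `k_max` auto-reduces with a
warning — with 60 SNPs, `k_max` drops from 5 to 4, for example. LD should
come from the same individuals as the association scan; a region built
with reference-panel LD is accepted but flagged, because external LD is a
known source of fine-mapping false positives.

## Two-sample Mendelian randomization

Instruments are lead *cis*-eQTLs: within 1 Mb of the gene's transcription
start site (inclusive at exactly 1 Mb) with `p < 1e-4` (strict, matching
the stated selection rule), one per gene and tissue. Exposure and outcome
records are harmonized to one effect allele: direct match, allele swap
(flip the outcome beta and frequency), or strand complement, in that
order. Palindromic pairs (A/T, C/G) carry no strand information in their
labels, so they are aligned purely by allele frequency and only when both
minor allele frequencies are below 0.42 (a common harmonization default;
the cutoff is configurable); otherwise the pair is dropped.

The causal estimate is the Wald ratio `beta_out / beta_exp`. Its default
standard error is the first-order delta method `|se_out / beta_exp|`, the
convention for single-SNP Wald MR; a flag adds the second-order
exposure-uncertainty term. The p-value is taken against the standard
normal, the usual choice in the two-sample summary-statistics setting
where the outcome study is large. The MR stage applies its own Bonferroni
gate at `alpha / (gene x tissue x trait tests)`.

Directionality is checked with the Steiger test in its
two-independent-samples form: each study's SNP-trait correlation is
reconstructed from the coefficient t statistic (`r = t / sqrt(t^2 + df)`),
and the Fisher-z statistic
`(atanh|r_exp| - atanh|r_out|) / sqrt(1/(n_exp-3) + 1/(n_out-3))` tests
equality of the correlations; `direction_ok` records whether the
instrument explains more variance in the exposure than in the outcome.
When an instrument is missing from an outcome dataset, a proxy is sought
at `r^2 >= 0.8` (highest r-squared wins; ties by variant id).

A structural limitation is inherited from the single-instrument design:
mediation cannot be separated from horizontal pleiotropy (scenario 5).
The generator simulates scenario 5 precisely so that this blind spot is a
*documented, tested property*: the Wald ratio converges to
`pleiotropy_effect / eqtl_effect` even though the mediation effect is
zero, and the test suite asserts that bias.

## Multiple-trait colocalization

For a GWAS trait (G), gene expression (E) and DNA methylation (M) over one
region, each SNP's evidence per trait is the Wakefield approximate Bayes
factor `sqrt(1 - r) * exp(r z^2 / 2)` with `r = W / (V + W)`, `V = se^2`
and prior variance `W = 0.15^2` (the coloc-family convention for
continuous traits; configurable per trait). A *configuration* assigns a
subset of the traits to causal groups — traits in one group share a causal
SNP, different groups occupy *distinct* SNPs (the two-trait "H3"
convention extended to three traits), omitted traits are unassociated.
Three traits admit 15 configurations; the engine is generic over 1–4
traits (2, 5, 15, 52).

The evidence of a configuration with groups `D_1..D_g` sums, over
assignments of distinct SNPs to groups, the product of per-SNP priors and
ABFs; per-SNP priors are 1e-4, 1e-6, 1e-7 for a SNP private to one trait,
shared by two, or shared by all three. The distinct-SNP sum is computed by
Möbius inversion over set partitions of the groups, which reduces it to
sums of products of per-SNP scores — linear in the number of SNPs — and is
evaluated with signed log-sum-exp for stability. The test suite proves
this equal (to 1e-10) to a brute-force loop over every SNP assignment.

Configurations are labelled by their group structure (`"GE.M"` = G and E
share a SNP, M has its own; `"null"` = nothing associated). Labels, not
hypothesis indices, are the public interface, because index numbering
varies between presentations. Decision rules follow the 0.8 convention:
`summed_ppa(result, c("G","E"))` adds every configuration in which G and E
share a group (GE, GE.M, GEM), and the all-share decision uses the GEM
configuration alone; both the summed G–E quantity and the GEM posterior
are reported, since "methylation is involved" can reasonably be read
either way.

Regions qualify when at least 50 SNPs (after a per-dataset MAF >= 0.05
filter, inclusive at the bound) are common to all datasets; smaller
regions return a structured skip rather than an error. The gene-centric
scan pairs every gene TSS and CpG within 1 Mb of the lead SNP.

## Orchestration

`run_discovery()` chains QC, per-trait eQTLWAS, the Bonferroni gate,
fine-mapping of each lead region (LD from the cohort's own dosages), MR
per gene x tissue x trait, and colocalization per gene x CpG. A failure in
one locus branch is logged and the run continues — at scan scale one
degenerate locus must not kill the run. `run_genomewide()` applies the
lookup-gate-MR-coloc chain to external eQTL catalogs and GWAS tables with
proxy substitution, and deliberately performs **no fine-mapping**, because
individual-level LD is unavailable in that mode. Reports embed an md5
fingerprint of the configuration, display thresholds at 2 significant
figures while storing full precision, and are byte-identical when re-run
with the same config and seed.

# The synthetic-data generator

The generator exists to give every stage data whose ground truth is known.
Its structural model:

* **Genotypes.** Two latent Gaussian first-order autoregressive haplotypes
  per individual, thresholded at the allele-frequency quantile and summed
  to dosages in {0, 1, 2}. The AR parameter `ld_rho` sets adjacent-SNP
  correlation on the latent scale, so LD decays geometrically with
  distance — a closed-form, controllable stand-in for haplotype structure.
  For scenario 4 the latent correlation across the designated SNP pair is
  calibrated by root-finding on the exact bivariate-normal orthant
  probability so the realised dosage r-squared hits its target (the tests
  require ±0.05).
* **Molecular traits.** Expression is `eqtl_beta x tissue_scale x dosage`
  plus Gaussian noise per tissue; methylation is generated on the logit
  scale and squashed through the logistic function, so values live
  strictly in (0, 1) like array beta-values.
* **Complex trait.** Sum of mediation effects times expression, any
  direct (pleiotropic) variant effect, additive age and sex effects, and
  Gaussian noise; an optional per-trait lognormal switch exponentiates the
  result. Expression is kept on its generative scale (noise SD defaults to
  1) so path coefficients multiply: with an eQTL effect of 0.4 and
  mediation of 0.3 the SNP-trait slope is 0.12, which the tests recover by
  OLS at n = 20,000.
* **Covariates.** Age uniform on a configurable range (default 7–11
  years, a childhood-cohort measurement window) and sex Bernoulli(0.5);
  the trait model adds both so that the adjusted scan has something real
  to adjust for.
* **Seeding.** One integer seed per specification; every stochastic block
  draws from its own derived sub-stream (`split_seed`), so identical
  specifications give bit-identical cohorts and adding replicates to one
  stage never shifts another.

Scenario defaults encode the mechanism contrasts: eQTL effect 0.4 per
allele, mediation 0.3 (scenario 1), a second mediating gene at 0.2
(scenario 2), a co-regulated null gene (scenario 3), an LD pair at target
r-squared 0.5 with a direct trait effect of 0.3 on the first member
(scenario 4), and a pleiotropic direct effect of 0.3 with zero mediation
(scenario 5). MAF defaults to 0.3 and the latent LD decay to 0.5 —
moderate, well-imputed-common-variant territory where all stages are
well-posed.

What the generator does **not** emulate: realistic haplotype panels or
recombination hotspots, imputation uncertainty (only the post-imputation
filters), relatedness and population structure, trans-eQTLs, non-Gaussian
phenotype tails beyond the lognormal switch, and cell-type heterogeneity
behind tissue effects. Passing tests therefore demonstrate calibration and
correctness of the statistical machinery under the stated generative
models, not performance on real cohort data.

# Problem sizes used by the test and acceptance suites

Calibration and recovery claims are checked at sizes where their
asymptotics hold but desk-scale runs stay quick: type-I error of the scan
from 200 null replicates of 500 variants at n = 300 (and 100 replicates in
the acceptance script); Steiger size from 1000 replicate pairs at
n = 2000 per study; Wald recovery from 200 scenario-1 cohorts at
n = 20,000; fine-mapping recovery from 100 regions of 10 SNPs at
n = 20,000; colocalization from 20 all-share and 10 LD-confounded regions
of 60–100 SNPs at n = 20,000, with the LD-margin trend probed at n = 2000
where posteriors do not saturate.

# Known limitations

* Exhaustive enumeration is exact but exponential in `k_max`; very large
  regions fall back to smaller `k_max` with a warning rather than
  switching to stochastic search.
* The Wald p-value uses the normal reference; with small outcome studies
  a t reference would be more conservative.
* Colocalization assumes one harmonizable effect allele per variant
  across the three datasets and discards irreconcilable variants.
* The two-sample MR stages treat the synthetic cohort as both exposure
  and outcome source when run in discovery mode; overlapping samples
  inflate weak-instrument bias in real data, though with the strong
  simulated instruments the effect is negligible.
* Regions of extensive LD (e.g. major histocompatibility complex) strain
  both fine-mapping and colocalization; results there warrant caution.
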