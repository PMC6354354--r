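# tissuemr

Causal triage of trait-associated gene-regulatory loci: eQTL-wide
association testing, Bayesian fine-mapping, two-sample Mendelian
randomization with Steiger directionality filtering, and Bayesian
multiple-trait colocalization of a complex trait with gene expression and
DNA methylation — plus a synthetic-cohort generator that simulates all
five mechanisms a trait-associated eQTL can reflect (single-gene
mediation, multi-gene mediation, co-regulation, LD confounding,
horizontal pleiotropy), so every stage is calibrated against known truth.

The package is aimed at statistical geneticists and molecular
epidemiologists who want a tested, reusable implementation of this
integrative workflow for GWAS and molecular-QTL summary statistics.

## The statistics at the core

* **eQTLWAS.** Per variant, OLS of phenotype on additive dosage with age
  and sex as covariates; p from the coefficient t statistic; Bonferroni
  gate at α/(instruments × traits). Phenotype QC removes values beyond
  ±4 SD; variants require imputation info ≥ 0.8 and MAF > 0.01.
* **Fine-mapping.** For z-scores *z* and LD matrix *R*, a causal
  configuration *S* (≤ 5 SNPs) has Bayes factor
  N(*z*; 0, *R* + n·σ²·R[,S]R[S,]) / N(*z*; 0, *R*); configurations are
  enumerated exhaustively, and per-SNP posterior inclusion probabilities
  (PIPs) sum the posterior over configurations containing each SNP.
* **Mendelian randomization.** One lead *cis*-eQTL per gene × tissue
  (within 1 Mb of the TSS, p < 1e-4) as instrument; Wald ratio
  β_out/β_exp with first-order delta SE; the Steiger test
  (Fisher-z on correlations reconstructed from t statistics) checks that
  the instrument explains more variance in expression than in the trait;
  proxy SNPs at r² ≥ 0.8 substitute missing instruments.
* **Multiple-trait colocalization.** Wakefield approximate Bayes factors
  per SNP and trait (√(1−r)·exp(r·z²/2), r = W/(V+W)); all 15
  sharing configurations for {GWAS trait, expression, methylation} scored
  with per-SNP priors 1e-4/1e-6/1e-7 and distinct SNPs across causal
  groups; regions need ≥ 50 common SNPs at MAF ≥ 5%; decisions use
  summed posterior probability of association (PPA) ≥ 0.8.

See the vignette (`vignettes/tissue-mr-pipeline.Rmd`) for the full model
description, parameter rationale, and limitations.

## Worked example

Simulate a single-gene-mediation cohort (eQTL effect 0.4 per allele on
GENE1 expression, mediation 0.3 on the trait) and run the full discovery
workflow:

```r
library(tissuemr)
spec   <- scenario_spec(1, n_individuals = 8000, n_snps = 60, seed = 19)
cohort <- simulate_cohort(spec)
report <- run_discovery(pipeline_config(seed = 19), cohort)
print(report)
#> discovery run: 60 scheduled tests, threshold 0.000833, 2 signal(s)
```

60 variant-trait tests were scheduled, so the gate is 0.05/60 ≈ 8.3e-4;
two variants pass and clump to one locus, led by the true causal SNP:

```r
report$leads[, c("variant_id", "pos", "beta", "se", "p")]
#>          variant_id     pos      beta         se           p
#> trait.30     snp_30 1290000 0.1243126 0.01779669 3.07359e-12
```

The slope 0.124 per allele recovers the generative path product
0.4 × 0.3 = 0.12. Fine-mapping the region puts the highest posterior on
the single-SNP configuration of the true variant:

```r
head(report$finemap[[1]]$configurations, 3)
#>         snp_set size   log_bf  log10_bf  posterior
#> 1        snp_30    1 21.71220  9.429489 0.49895484
#> 2 snp_26,snp_30    2 24.87779 10.804287 0.20045030
#> 3 snp_30,snp_39    2 22.09933  9.597616 0.01245477
```

MR then estimates the effect of GENE1 expression on the trait — the Wald
ratio 0.309 ± 0.044 matches the generative mediation effect 0.3, and the
Steiger test confirms the expression-to-trait direction:

```r
report$mr[, c("exposure", "beta_mr", "se_mr", "p", "direction_ok")]
#>   exposure   beta_mr      se_mr            p direction_ok
#> 1    GENE1 0.3090678 0.04424636 2.845386e-12         TRUE
```

Finally, colocalization of trait, expression and methylation identifies
the shared causal variant:

```r
Filter(function(r) r$status == "ok", report$moloc)[[1]]
#> moloc: 60 common SNPs, 15 configurations
#>  GEM   EM EM.G   GM    M
#>    1    0    0    0    0
#> summed PPA(G,E) = 1.000  [colocalized]
#> PPA(GEM) = 1.000  [all three share]
```

All three traits share one causal SNP (configuration GEM), as simulated.

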