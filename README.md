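# placmed

Does the genetic risk of hypertension that a mother carries lower her
baby's birth weight by raising her blood pressure — or by limiting the
growth of the placenta? `placmed` is an R package for analysing
mother–father–child trio cohorts around that question. It implements the
full analysis path from phased genotypes and GWAS summary statistics to a
causal mediation decomposition of the effect of a maternal
blood-pressure-increasing polygenic score (PGS) on offspring birth weight,
with placental weight as the mediator, together with a
ground-truth-retaining synthetic cohort generator so the entire pipeline can
be exercised and validated without access to any individual-level data.

It is intended for perinatal epidemiologists and statistical geneticists
working with small, deeply phenotyped birth cohorts (serial antenatal blood
pressure, serial ultrasound fetal biometry, placental weight at delivery,
trio genotypes).

## What it computes

**Polygenic scores.** Classic clumping + thresholding: variant QC (call
rate < 95%, MAF < 0.01, Hardy–Weinberg p < 1e-5 on founders, imputation
DR2 < 0.7, autosomes only), greedy LD clumping (defaults r² = 0.1 within
±1000 kb, PLINK-style), p-value thresholds 1e-6 … 1e-3, and the
dosage-weighted score

> PGS_i = Σ_v d_iv β_v

(z-scaled across mothers), plus unweighted SBP-increasing allele counts
subdivided by vasculature annotation, and pleiotropy-excluded variants
(BMI/T2D/HbA1c associations at 1e-8/1e-6/1e-4).

**Haplotype decomposition.** Per mother–child pair, the BP-increasing
alleles are split into maternal-transmitted, maternal-non-transmitted and
paternal-transmitted counts; double-heterozygous sites are resolved by
local haplotype sharing over a flanking window. Non-transmitted maternal
alleles can only act through the intrauterine environment, which is what
makes this decomposition informative.

**Mediation.** The core model object: for z-scaled exposure X (PGS),
mediator M (chart-standardized placental weight) and outcome Y
(chart-standardized birth weight), with log pre-pregnancy BMI as confounder C,

> M = α₂ + aX + gC + ε₂  
> Y = α₃ + c′X + bM + hC + ε₃

fitted by OLS. ACME = a·b, ADE = c′, total = a·b + c′ (exact in this
linear, no-interaction model), proportion mediated = ACME/total.
Uncertainty by quasi-Bayesian Monte Carlo (draws from the asymptotic normal
of the coefficients), and a sensitivity analysis giving ACME as an analytic
function of ρ, the correlation between mediator- and outcome-model errors
(ACME crosses zero exactly at the observed residual correlation).

**Fetal growth velocity.** Per-fetus penalized cubic regression splines
(GAM, GCV smoothness) over serial estimated fetal weight, weekly EFW on the
interior integer-week grid, weekly velocity as first differences,
cross-sectional z-normalization per week, and regressions of z-velocity on
PGS tertile every two weeks from 22 to 36 (Bonferroni threshold
0.05/8 = 6.25e-3).

## Worked example

Simulate the default synthetic study (93 trios, 3000 variants in LD blocks,
mediation paths a = −0.396, b = 0.661, c′ = −0.049) and run the whole
pipeline:

```r
library(placmed)
rep <- run_pipeline(pipeline_config(seed = 101, n_sims = 1000))
print(rep$mediation)
```

```
Linear causal mediation analysis (quasi-Bayesian, 1000 draws)
  exposure: pgs_z  mediator: pw_zz  outcome: bw_zz  n = 93
              estimate ci_low ci_high p_value
acme           -0.2246 -0.381 -0.0896   0.002
ade            -0.0375 -0.205  0.1375   0.712
total          -0.2621 -0.461 -0.0720   0.008
prop_mediated   0.8568  0.411  2.2461   0.008
```

A one-SD higher maternal BP-PGS lowers birth weight by 0.26 SD in this
replicate; 86% of that effect runs through placental weight (ACME −0.22,
significant), while the direct path is small and indistinguishable from
zero — the generating structure is recovered. Sensitivity:

```r
s <- sensitivity(rep$mediation)
attr(s, "rho_tilde")
#> 0.618  — the ACME would only vanish if mediator and outcome residuals
#>          were correlated at rho ≈ 0.62
```

The per-week velocity regressions (`rep$velocity$regressions`) show the
characteristic late-gestation emergence: estimates near zero at week 22
(+0.01) strengthening towards week 32–36 (−0.19 to −0.24 SD per tertile),
because the mediator is wired to third-trimester growth only.

## Package layout

| file | contents |
|---|---|
| `R/io.R` | readers/writers: phased VCF + pedigree, summary stats, phenotypes, chart, annotation, ultrasound |
| `R/synthetic.R` | LD-blocked haplotype pool, trio, phenotype, summary-stat and ultrasound simulators (ground truth retained) |
| `R/pgs.R` | QC, LD clumping, thresholding/scoring, allele orientation, subdivided and pleiotropy-excluded scores |
| `R/haplotype.R` | transmitted/non-transmitted allele-count decomposition |
| `R/phenotype.R` | PP/MAP, gestation-period means, eligibility, chart standardization |
| `R/growth.R` | growth-curve GAMs, weekly velocity, tertiles, per-week regressions |
| `R/mediation.R` | `mediate_linear()` S3 model (`linmed`) with print/summary/coef/confint/plot, `sensitivity()`, `mediation_battery()` |
| `R/association.R` | standardized regressions, Bonferroni, AIC model choice, power/sample size |
| `R/pipeline.R` | `run_pipeline()` orchestration, config, reporting |

The methods vignette (`vignettes/placmed-methods.Rmd`) documents the model,
the generator's assumptions and every numerical design choice.
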