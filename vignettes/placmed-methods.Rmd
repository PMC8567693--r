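---
title: "placmed: models, synthetic data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{placmed: models, synthetic data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placmed)
```

## The scientific question and the model

Maternal hypertension-risk alleles are associated with lower offspring
birth weight, yet in cohorts of normotensive pregnant women the polygenic
score (PGS) is typically *not* associated with measured blood pressure.
`placmed` implements the alternative causal route: BP-increasing variants —
many of which act in vascular development and function — restrict the
growth of the placenta, a profoundly vascular organ, and the placenta in
turn limits third-trimester fetal growth.

The estimand is a classical linear mediation decomposition. With z-scaled
maternal PGS $X$, chart-standardized placental weight $M$, chart-standardized
birth weight $Y$ and log pre-pregnancy BMI $C$ (the one confounder retained,
entered in both models):

$$M = \alpha_2 + aX + gC + \varepsilon_2, \qquad
  Y = \alpha_3 + c'X + bM + hC + \varepsilon_3 .$$

The average causal mediation effect is $\mathrm{ACME} = ab$, the average
direct effect $\mathrm{ADE} = c'$, and in this linear no-interaction model
they sum exactly to the total effect. The proportion mediated is
$ab/(ab + c')$. Identification rests on sequential ignorability — no
unmeasured confounding of the exposure–mediator, exposure–outcome and
mediator–outcome relations given $C$ — which is untestable and therefore
paired with a sensitivity analysis (below).

### Quasi-Bayesian intervals

`mediate_linear()` fits both models by OLS and draws `n_sims` coefficient
vectors from $N(\hat\theta, \widehat{\mathrm{Var}}(\hat\theta))$ of each
model, recomputing ACME/ADE/total/proportion per draw. Point estimates are
the plug-in values from the fitted coefficients; intervals are percentile
intervals of the draws; two-sided p-values are
$2\min(\Pr(\le 0), \Pr(\ge 0))$ over draws, floored at $2/\texttt{n\_sims}$
— the Monte Carlo resolution limit, reported as such rather than as an
exact zero.

The per-draw proportion mediated $ab/(ab+c')$ is unstable when the drawn
total effect is near zero; draws with $|ab + c'| <$ `prop_eps` are excluded
from that one interval and tallied in the fit object. The same instability
is why any *averaging* of proportions across replications in this package
uses the ratio of means, $\overline{\mathrm{ACME}}/\overline{\mathrm{total}}$,
rather than the mean of per-replicate ratios: at $n = 93$ the total-effect
estimate has a standard error around 0.1 against a value near $-0.3$, and
the mean of ratios is inflated by several points purely through
near-null denominators.

### Sensitivity to sequential ignorability

Let $\rho$ be the correlation between the mediator-model and outcome-model
errors. For the linear structural equation model the bias-corrected ACME
has the closed form

$$\mathrm{ACME}(\rho) = a\,\frac{\sigma_1}{\sigma_2}
  \left(\tilde\rho - \rho\sqrt{\frac{1-\tilde\rho^2}{1-\rho^2}}\right),$$

where $\tilde\rho$, $\sigma_1$, $\sigma_2$ are the observed correlation and
standard deviations of the residuals of the *total-effect* outcome model
($Y$ on $X, C$) and the mediator model. Two exact consequences are used as
tests: $\mathrm{ACME}(0)$ equals the baseline ACME (by the
Frisch–Waugh–Lovell identity $\hat b = \tilde\rho\,\sigma_1/\sigma_2$), and
the curve crosses zero at $\rho = \tilde\rho$ precisely. On calibrated
synthetic cohorts $\tilde\rho \approx 0.6$: the mediation conclusion would
only be overturned by an unmeasured mediator–outcome confounder inducing a
residual correlation of that size.

## The synthetic cohort generator

The study the package is calibrated to is not publicly deposited, so the
generator is a first-class module whose defaults *are* the study
conditions: 93 mother–father–child pairs, and generating paths equal to the
standardized estimates the analysis is designed to recover,
$a = -0.396$, $b = 0.661$, $c' = -0.049$ (so the true ACME is $-0.262$, the
true proportion mediated $84\%$).

* **Haplotypes.** 60 blocks × 50 variants (3000 SNPs). Within a block all
  variants share a MAF drawn from $U(0.1, 0.5)$ and are generated by a
  copying chain: each allele copies its left neighbour with probability
  $\sqrt{r^2_{\text{target}}}$ (default target 0.8), else is a fresh
  Bernoulli draw — for equal-MAF Bernoulli variables the copying
  probability equals the allelic correlation, so adjacent $r^2$ lands on
  the target without tuning. Blocks are independent; positions are 1 kb
  apart within blocks with 5 Mb gaps, cycling over chromosomes 1–22.
* **Trios.** Parents draw two pool haplotypes; the child receives one
  maternal and one paternal haplotype uniformly, with **no recombination**
  inside the region. This keeps the transmitted-haplotype identity exact in
  the stored truth, making the local-haplotype-sharing resolver testable
  against a gold standard; it is a documented simplification — real data
  would add switch errors and recombinant flanks, so resolution rates on
  real cohorts will be lower than the near-perfect rates seen here.
* **Genetic architecture.** One causal variant in each of the first 40
  blocks; causal effects are scaled so the liability explains the SBP
  heritability target 0.0569 of a unit-variance trait (DBP 0.04, MAP
  0.0496, PP 0.0438 by rescaling). Emitted summary statistics are
  LD-propagated marginal effects plus sampling noise at a notional GWAS
  n of 136,000, with p-values from the corresponding z-statistics; half the
  rows are emitted with effect/other alleles swapped (beta negated) to
  exercise allele alignment.
* **Phenotypes.** Mediator and outcome follow the structural model above
  with residual SDs solved so both are unit-variance; BMI is log-normal
  (the pipeline log-transforms); weights are back-transformed to grams via
  the packaged reference chart so chart standardization is an exact inverse
  in the noiseless direction. Antenatal BP readings follow the checkup
  schedule with only a small genetic variance share (default 0.005) —
  reproducing the cohort-scale *null* PGS–measured-BP association.
* **Ultrasound.** Each fetus follows a logistic weight curve
  ($K \approx 5000$ g, midpoint week 33, rate 0.16); after week 30 the
  weekly increment is shifted by `velocity_link` (default +40 g/week per SD
  of mediator), so a smaller placenta slows late growth — velocity and
  mediator are uncorrelated before week 30 by construction. Scan times
  follow the antenatal checkup schedule (every 4 weeks to 24, every 2 weeks
  to 36, weekly beyond) with jitter and dropout, 6–12 per fetus, denser in
  the third trimester as in the cohorts this emulates; measurement noise is
  5% multiplicative.

What the generator does **not** emulate: population stratification,
imputation uncertainty (DR2 is emitted as 1.0), recombination, assortative
mating, fetal-genotype direct effects separate from transmission, missing
phenotype data, and real LD block structure. Passing tests therefore
demonstrate correctness of the estimators under the stated model, not
robustness to those real-data complications.

## Pipeline conventions and numerical choices

* **QC**: call rate ≥ 0.95 over all samples; MAF ≥ 0.01 and the 1-df
  Hardy–Weinberg chi-square ($p \ge 10^{-5}$) on founders only; DR2 ≥ 0.7
  where available; autosomes only.
* **Clumping** uses the mothers' dosages of the analysis cohort itself as
  the LD reference (base and target are the same population); ties on p are
  broken by (chromosome, position) so results are deterministic. Allele
  matching between summary statistics and genotypes is exact (forward or
  swapped-with-sign-flip); strand flips are *not* attempted and mismatches
  are dropped with a warning, appropriate when base and target come from
  the same genome build and population.
* **Threshold selection**: scores are built at p ≤ 1e-6, 1e-5, 1e-4, 1e-3;
  all four are reported and the one maximizing adjusted R² against the
  named analysis trait (placental weight by default) is marked selected.
  Degenerate scores (no variants, or zero variance) are flagged, never NaN.
* **Haplotype resolution window**: ±25 variants, configurable. The
  double-heterozygote rule takes the child haplotype with the longer exact
  flanking match to the allele-consistent maternal haplotype; exact ties
  are reported unresolved and excluded from all three counts (the tally is
  kept per pair). Duos yield maternal counts only.
* **Chart standardization** keys on the completed (floored) gestational
  week; parity is binarized. z-scaling throughout uses the n−1 variance;
  with two observations a cross-sectional z is therefore ±1/√2.
* **Growth curves**: penalized cubic regression splines (`mgcv::gam`,
  GCV), basis dimension capped at 6. The cap matters: unconstrained GCV on
  6–12 noisy points occasionally interpolates, which wrecks weekly
  velocity; 6 basis functions are ample for a sigmoidal weight curve, and
  on noiseless input the penalty vanishes so polynomial truth is
  reproduced at the grid points. The weekly grid runs from the ceiling of
  the first to the floor of the last observed week — never extrapolated —
  and velocity telescopes exactly to the endpoint difference. A natural
  smoothing spline, by contrast, is exact only *at* observation knots near
  the boundary, which is why grids are observation-aligned.
* **Velocity regressions** enter the PGS tertile as a numeric 1–2–3
  covariate ("change per stratum increase"), every 2 weeks from 22 to 36,
  Bonferroni threshold 0.05/8 = 6.25e-3.
* **Power**: the minimum n for the regression F test solves the
  noncentral-F power equation with ncp $= f^2(u + v + 1)$ by bisection;
  with α = 0.05, power 0.80, R² = 0.15, u = 1 and $f^2 = R^2/(1-R^2)$ this
  gives n = 47. A flag allows $f^2 = R^2$ directly, since a stated
  "R²" can be fed to power software under either convention.
* **Model choice** between linear and quadratic BP–birth-weight relations
  is by AIC with a residual-normality diagnostic; a global linear-model
  assumption battery is intentionally out of scope.
* **Determinism**: every stochastic routine takes a seed; the pipeline
  fans one global seed out to fixed per-stage offsets, so a stage can be
  re-run in isolation and identical configuration yields byte-identical
  output files (run logs contain no timestamps).

## Problem sizes used by the test-suite and acceptance runs

Unit and property tests run on reduced cohorts (25–60 trios, 3–20 blocks)
chosen to exercise every code path at interactive speed; calibration
properties use the full 93-trio default. The interval-coverage property
uses 500 replicates of the structural-equation layer at n = 93 (93–97%
observed coverage band); the acceptance computation averages 80 full
pipeline replicates. These sizes are the package's own reproducibility
conventions.

## Known limitations

* The vasculature annotation tables shipped under `inst/extdata` are
  synthetic stand-ins reproducing only the documented marginal structure
  (41 = 18/12/11 with 7 DBP-discordant; 67 = 21/30/16); they carry no real
  variant identities.
* The mediation machinery covers a single continuous mediator and outcome,
  no exposure–mediator interaction, OLS only — matching the analysis it
  implements, not the general mediation literature.
* Haplotype-sharing resolution assumes correctly phased input; phasing
  switch errors would silently become unresolved or misattributed sites.
* The reference chart is an input; no national chart values are bundled.
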