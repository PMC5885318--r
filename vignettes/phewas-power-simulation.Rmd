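---
title: "Simulating power and Type I error for phenome-wide association studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating power and Type I error for phenome-wide association studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phewaspower)
```

## The problem

A phenome-wide association study (PheWAS) tests genetic variants against a
large collection of phenotypes — EHR diagnosis codes, clinical laboratory
values, epidemiological measurements. Because the phenotypes are collected
opportunistically, their effective sample sizes vary enormously: a diagnosis
code may have 11 cases or 12,000, a laboratory value may be measured on 48
people or 25,000. Power is therefore not a single number per study but a
surface over case counts, case:control ratios, allele frequencies and effect
sizes. `phewaspower` estimates that surface by direct Monte Carlo
simulation, and provides the companion EHR phenotyping step that decides
which diagnosis codes are worth testing at all.

## The simulation model

### Genotypes

Each SNP is biallelic with minor allele frequency $q \in (0, 0.5]$ and
genotypes coded additively as minor-allele counts $g \in \{0, 1, 2\}$.
Individuals are drawn i.i.d. from Hardy-Weinberg equilibrium,
$P(g) = \big((1-q)^2,\; 2q(1-q),\; q^2\big)$, as unrelated population
samples: no linkage disequilibrium between SNPs, no stratification, no
relatedness. Drawing each individual's genotype directly from the trinomial
is equivalent, under HWE, to drawing two alleles independently, and is
simpler to verify (`hwe_genotype_probs()` is the exact oracle for a
goodness-of-fit test at any $n$).

### Binary traits: penetrance functions and retrospective sampling

Effect sizes are expressed as *penetrance functions*
$(f_0, f_1, f_2) = P(\text{case} \mid g)$. Two parameters fix the triple:

* `baseline` — $f_0$, the disease probability among non-carriers. This is
  the intercept of the risk model and doubles as the disease prevalence in
  the genotype-0 stratum; the default is 0.1. We interpret it as a
  probability on the risk scale, not a logistic intercept (an intercept of
  0.1 on the logit scale would mean 52% prevalence, which is not a plausible
  reading for a "constant disease prevalence" parameter).
* `penetrance` — $f_2$, the risk for homozygous carriers. The heterozygote
  sits at the midpoint, $f_1 = (f_0 + f_2)/2$: additive on the risk scale,
  matching the additive genetic model used throughout. The risk allele is
  always the minor allele; protective effects are out of scope.

Cohorts with a fixed case quota are sampled *retrospectively*: draw
$g \sim \mathrm{HWE}(q)$, then status $\sim \mathrm{Bernoulli}(f_g)$, and
accept individuals into the case or control stratum until both quotas are
filled (draws beyond a filled stratum are discarded; a cap of $10^7$ draws
guarantees termination when a degenerate penetrance function makes a
stratum unfillable). By Bayes' rule the accepted case stratum has genotype
distribution $\propto \mathrm{HWE}(g)\, f_g$ and the control stratum
$\propto \mathrm{HWE}(g)(1 - f_g)$ — `expected_case_genotype_dist()` gives
the closed form, which the test suite checks by chi-square at $10^5$ cases.
A ratio of $r$ means $r$ controls per case ("1:2" = twice as many controls);
non-integer products round to the nearest control count.

### Quantitative traits: a liability-calibrated mean shift

The same penetrance function drives the quantitative generator through a
liability-threshold calibration. The trait is
$Y = \beta g + \varepsilon$, $\varepsilon \sim N(0,1)$, with

$$\beta = \tfrac{1}{2}\left[\Phi^{-1}(1 - f_0) - \Phi^{-1}(1 - f_2)\right],$$

chosen so that, against the fixed threshold $\Phi^{-1}(1 - f_0)$,
non-carriers fall in the upper tail with probability $f_0$ and homozygous
carriers with probability $f_2$. Carriers are thereby enriched at the upper
end of the trait distribution, which is exactly the behaviour the binary
penetrance describes, and the model admits a closed-form power oracle
(below). For the defaults, `liability_effect_size(0.1, 0.15)` = 0.1226 and
`liability_effect_size(0.1, 0.3)` = 0.3786 trait-SD per allele.

### Replicate layout and the testing battery

Each replicate dataset mirrors a small PheWAS: 4 SNPs and 10 phenotypes
(binary) or 1 phenotype (quantitative), with exactly one signal
SNP-phenotype pair. The 3 noise SNPs are drawn at the signal MAF but
independently of everything; the 9 noise phenotypes are uniform random
permutations of the case/control labels, so every phenotype column has
identical case counts. All $4 \times 10 = 40$ (or $4$) pairs are tested:

* binary — logistic regression $\mathrm{logit}\,P(\text{case}) = b_0 + b_1 g$,
  fitted by Newton/IRLS on the genotype-aggregated sufficient statistics
  (per-genotype totals and case counts), tolerance $10^{-8}$ on the
  log-likelihood, 50 iterations max, with step-halving; Wald two-sided
  p-value on $b_1$;
* quantitative — ordinary least squares with a two-sided $t$-test on the
  slope ($n - 2$ df).

The Wald test (rather than likelihood-ratio or score) matches what generic
regression output reports and what PheWAS pipelines typically consume.
Constant genotypes, single-class phenotypes and (quasi-)separation —
detected as failure to converge, a non-finite standard error, or
$|\hat b| > 15$ — yield `converged = FALSE`; power runs count such tests as
non-significant and tally them in `n_nonconverged`. This choice is
conservative in extreme cells (e.g. 10 cases at MAF 0.01, where most noise
fits are quasi-separated).

### Power, Type I error, and thresholds

With `replicates` $R$ per grid cell (default 1000),
power $= \#\{\text{replicates with signal-pair } p < \alpha\}/R$ and
Type I error $= \#\{\text{noise-pair tests with } p < \alpha\}/(R \times 39)$
(or $\times 3$). Both carry binomial Monte-Carlo standard errors. The
default per-test thresholds are $\alpha = 0.01/40 = 0.00025$ for the binary
battery and $\alpha = 0.004$ for the quantitative battery. The quantitative
default is deliberately a fixed constant rather than $0.01/4$: it is the
threshold at which this 4-test design's reference power surfaces are
conventionally quoted, and every calibration target in the test suite uses
it. Both defaults are explicit in every output row and freely overridable
(`alpha` in `sim_design()`, `family_level` in config files, which *is*
divided by the test count).

### The closed-form quantitative oracle

For the linear model above, the slope estimator has asymptotic variance
$1/(n \,\mathrm{Var}(g))$ with $\mathrm{Var}(g) = 2q(1-q)$, so

$$\text{power} \approx \Phi(-z_{1-\alpha/2} + \lambda) +
  \Phi(-z_{1-\alpha/2} - \lambda), \qquad
  \lambda = \beta\sqrt{2q(1-q)\,n}.$$

`analytic_power_linear()` implements this; the acceptance suite verifies
simulation-vs-closed-form agreement within 3 Monte-Carlo standard errors on
10 cells chosen (analytically, in advance) to have power between 0.1 and
0.9, where the comparison is informative. A two-proportion normal
approximation on the case/control allele-frequency contrast plays the same
oracle role for binary cells (in the test helpers).

## Determinism and parallelism

Every replicate's seed derives from `(master_seed, cell_index, replicate)`
through a 31-bit multiplicative mix (`replicate_seed()`), exact in doubles
and valid for `set.seed()`. Grid results are therefore identical for any
worker count and any execution order; `run_grid(..., workers = k)` forks
with `parallel::mclapply` but never changes the numbers.

## Default grids

Printed power surfaces for this class of design span roughly: cases
{10, 20, 50, 100, 200, 500, 1000}; ratios {1:1, 1:2, 1:4}; MAF
{0.01, 0.05, 0.10, 0.25}; penetrance {0.10, 0.15, 0.20, 0.25, 0.30};
quantitative $n$ from 10 to 25,000. Config files take arbitrary axis lists;
none of these values is hard-coded.

## What the synthetic EHR generator does and does not emulate

`synth_ehr()` emulates sparse longitudinal coding: each patient carries each
ICD-9 code with probability `prevalence`; carriers receive
$\mathrm{Poisson}(\lambda)$ coded visits dated uniformly over the study
window. This gives the rule-of-three case definition a closed-form expected
case count, $n \cdot \mathrm{prev} \cdot P(\mathrm{Pois}(\lambda) \ge 3)$,
used as the test oracle (two visits drawn on the same calendar date collapse
to one, a bias far inside the 4-standard-deviation test band at the default
2-year window). It does *not* emulate correlated comorbidities, visit
clustering, coding drift over time, censoring by enrolment date, or
hierarchical ICD-9 structure — so passing tests show the *procedure* is
correct, not that the generator reproduces any real health system's code
frequency distribution. "Independent visits" means distinct calendar dates
for that patient/code pair; codes match exactly (no hierarchy rollup or
phecode grouping).

## Numerical and design notes

* Genotypes at `maf = 0` are allowed (degenerate all-zero vector) for null
  testing; `maf > 0.5` is rejected — the minor allele is the rarer one.
* The logistic fit aggregates to the 3-genotype sufficient statistics before
  iterating, so it is exactly permutation-invariant and costs O(1) per
  Newton step regardless of $n$.
* Zero residual variance in the linear fit (an exactly collinear trait)
  returns $p = 0$ with a diagnostic note rather than an error; a constant
  trait returns slope 0, $p = 1$.
* Non-converged tests are never dropped from the Type-I denominator: the
  denominator is always $R \times$ (noise pairs), so conservative cells show
  *low* Type I error rather than a shrunken test count.

## Simulation sizes in the test suite

The shipped tests run each calibration at sizes chosen to keep the whole
suite in a few minutes while leaving the conclusions sharp: Type-I
calibration cells at the full 1000 replicates (39,000 noise tests per binary
cell), trend and threshold checks at 200 replicates per cell,
oracle-agreement checks at 300-400 replicates, and distributional checks at
$10^5$-$10^6$ draws. `scripts/acceptance.R` runs the headline 1000-case
binary cell at the full 1000 replicates.

## Known limitations

* **Wald conservativeness in sparse cells.** With few expected minor-allele
  carriers (MAF 0.01 with 50-200 cases), the Wald logistic test is severely
  conservative at phenome-wide thresholds: quasi-separation is common and
  the attainable test statistics rarely reach $|z| > 3.66$, so the empirical
  Type I error falls well *below* 0.00025 — often to zero — rather than
  matching it. This is the Hauck-Donner phenomenon, and it is a property of
  Wald-based PheWAS pipelines generally, not of this implementation: the
  test suite documents it by asserting the two-sided binomial calibration
  band in exactly those cells and letting the sparse ones fail low. Power in
  such cells is correspondingly conservative. A Firth or score test would
  behave differently; both are out of scope.
* **Ratio "negligibility" is a saturation statement.** Adding controls does
  add information: in mid-power cells the two-proportion oracle shows
  spreads of 0.2-0.4 between 1:1 and 1:4 designs at fixed cases. The
  case:control ratio is negligible *in the saturated regime* (power near 0
  or 1), which is where the recommendation "case count, not ratio, drives
  power" applies; the acceptance check of ratio-invariance is therefore run
  at a saturated cell (500 cases, MAF 0.25, penetrance 0.25).
* No covariates, gene-environment interaction, non-additive penetrance,
  linkage disequilibrium, relatedness, or rare-variant aggregation; the
  quantitative generator is one faithful reading of tail-enrichment
  phenotype generation, chosen for its closed-form oracle.
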