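---
title: "Calibrating polygenic risk prediction with Mondrian cross-conformal prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating polygenic risk prediction with Mondrian cross-conformal prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mondrianprs)
```

## The problem

A polygenic risk score (PRS) is a weighted sum of allele dosages,
$s_i = \sum_j \beta_j x_{ij}$, with weights taken from a discovery GWAS. It
is a *relative* measure: it ranks individuals, but it does not by itself say
how much an individual prediction can be trusted, and the usual remedy —
declaring the top $x\%$ of scores "high risk" for some arbitrary $x$ — gives
no per-individual error guarantee. This package wraps a conformal-prediction
calibration layer around the PRS so that every individual receives a pair of
class-conditional p-values and, at any user-chosen error rate $\alpha$, a
prediction *region* whose long-run error is controlled at $\alpha$ per class.

## The method

**Nonconformity.** A logistic regression of case-control status on the PRS
(and optional covariates) is fitted on a proper training set. Writing
$d(x)$ for its linear predictor (log-odds) and encoding case as $y = +1$,
control as $y = -1$, the nonconformity measure is

$$\mathrm{NCM}_y(x) = -\,y \cdot d(x),$$

large when the individual looks unusual for the hypothesized class. Using
the linear predictor rather than the predicted probability changes nothing
(the two are monotone-equivalent, so every rank, p-value and region is
identical) but is numerically safer in the tails.

**Mondrian (class-conditional) p-values.** With a calibration set disjoint
from the training set, the p-value of test individual $i$ for class $y$
compares its nonconformity against the calibration members *of that class
only*:

$$p^i_y \;=\; \frac{\#\{j \in \text{cal},\, y_j = y : \mathrm{NCM}_j \ge \mathrm{NCM}_i\} + c}{N_{\mathrm{cal},y} + 1}.$$

Class-conditioning is what makes the guarantee hold *per class* under the
severe case-control imbalance typical of population cohorts (prevalence
0.01–0.2); a pooled calibration set (`icp_pvalues()`) systematically
inflates minority-class p-values, which the test suite demonstrates. The
counting constant is $c = 1$ by default — the standard inductive-conformal
convention that counts the test point itself, keeps p-values in $(0, 1]$ and
guarantees conservative validity. `bare_count = TRUE` switches to the
bare count $c = 0$; the difference is $O(1/N_{\mathrm{cal}})$ and both are
exposed because published descriptions of the method are ambiguous on this
point.

**Cross-conformal averaging.** Rather than sacrificing one fixed calibration
split, the training sample is partitioned into $n$ stratified folds
(default $n = 5$); each fold serves once as the calibration set for a scorer
fitted on the remainder, and the $n$ p-value pairs of a test individual are
averaged. Stratification by class is deliberate: unstratified folds can
produce single-class calibration sets at prevalence 0.01, which are
unusable. Averaged cross-conformal p-values carry no exact finite-sample
guarantee — a known property of cross-conformal methods — so validity is
asserted empirically, which is what the reliability machinery below is for.

**Regions, confidence, credibility.** At error rate $\alpha$ the region is
$\Gamma^\alpha = \{y : p_y > \alpha\}$, giving four outcomes: predicted
case ($p_1 > \alpha \ge p_0$), predicted control ($p_0 > \alpha \ge p_1$),
uncertain (both above), or empty/unpredictable (both at or below).
Confidence is $1 - \min(p_0, p_1)$ (the greatest $1 - \alpha$ at which the
region is a single class) and credibility is $\max(p_0, p_1)$ (the smallest
$\alpha$ at which it is empty). With $p_0 = 0.01$, $p_1 = 0.8$ an individual
is predicted a case with credibility 0.8 and confidence 0.99. Point-prediction
ties ($p_0 = p_1$) go to control — a deterministic, conservative rule,
configurable via `tie =`.

```{r example}
prediction_region(tibble::tibble(p0 = 0.01, p1 = 0.8), alpha = 0.05)
```

## The synthetic cohort

Real cohort genotypes cannot be redistributed, so the package ships a
generator whose defaults define the study conditions used throughout the
tests:

| parameter | default | meaning |
|---|---|---|
| `n_individuals` | 10,000 | cohort size |
| `m_snps` | 20,000 | biallelic SNPs, 1 kb apart on one chromosome |
| `polygenicity` | 0.01 | fraction of SNPs that are causal |
| `heritability` | 0.5 | liability-scale $h^2$ |
| `prevalence` | 0.05 | population prevalence $K$ |
| `maf_low`, `maf_high` | 0.05, 0.5 | uniform allele-frequency spectrum |
| `ld_block_rho` | 0 | linkage equilibrium by default |
| `discovery_proportion` | 0.5 | fraction used for the discovery GWAS |

Genotypes are Hardy–Weinberg draws; with `ld_block_rho > 0` the two
haplotypes of each individual follow a latent Gaussian AR(1) process within
blocks, so pairwise $r^2$ decays with distance while marginal frequencies
are preserved — this exists so the 100-kb pruning window has nontrivial
work, not as a model of real LD.

Phenotypes follow the additive liability-threshold model: causal effects are
drawn i.i.d. $N(0, h^2/m_c)$ on standardized dosages and then rescaled so
the *sample* variance of the genetic value is exactly $h^2$. This variance
calibration (standard in GWAS simulators) matters: without it, at
polygenicity 0.001 the realized genetic variance is $h^2 \chi^2_{20}/20$,
and the realized prevalence can drift to a third of its nominal value. The
liability is $l = g + e$ with $e \sim N(0, 1 - h^2)$, and an individual is a
case exactly when $l > \Phi^{-1}(1 - K)$. The simulation is
population-based: no ascertainment or case oversampling, so the sample case
fraction equals $K$ up to binomial noise.

**What the generator does not emulate:** real LD structure (haplotype
blocks, recombination hotspots, an external LD reference panel), allele
frequency–effect size coupling, population structure and relatedness,
genotyping error and imputation uncertainty, covariates such as age and sex,
and case ascertainment. Passing tests therefore demonstrate the calibration
machinery and the qualitative behavior of the pipeline across architectures,
not absolute performance on any real cohort.

## GWAS and PRS construction

The discovery GWAS is a per-SNP univariate logistic regression (Wald test),
computed by a vectorized two-parameter Newton solver and unit-tested against
`glm()`. Two edge cases get explicit handling: monomorphic SNPs are reported
with $\beta = 0$, $p = 1$; and (quasi-)separated SNPs — strong effects at
low prevalence routinely empty one cell of the 2×2 table, where the Wald
statistic degenerates toward $p = 1$ (the Hauck–Donner effect) — fall back
to the logistic score test for the p-value and a slope-ridge fit for a
finite effect estimate. Without that fallback the strongest causal signal
can be silently excluded from the PRS.

Selection is thresholding then pruning: keep SNPs with $p < 0.05$ and minor
allele frequency $\ge 0.01$, then greedily remove one member of every pair
with $r^2 \ge 0.1$ inside a 100-kb sliding window. The removal rule keeps
the smaller-p SNP (clumping-like; a p-blind `keep-first` mode reproduces
PLINK `--indep-pairwise` behavior), and pair selection within a window is
deterministic: highest $r^2$ first, ties by index order, p ties resolved
against the larger position. The window slides in base pairs (default step
50 bp, snapped to a grid with duplicate windows skipped); a variant-count
step is available through `step_variants` since step conventions differ
between tools. LD is computed from the supplied genotypes — in simulation,
the target sample stands in for an external reference panel.

The PRS is $\sum_j \beta_j x_{ij}$ over the surviving SNPs, with effect
alleles reconciled against the genotype orientation (swapped alleles flip
the dosage; irreconcilable SNPs are dropped with a warning, and more than
50% irreconcilable aborts as a likely strand or build mismatch).

## Evaluation

`reliability_curve()` runs stratified outer 5-fold cross-validation: each
fold is predicted once by a cross-conformal predictor (and by a plain
logistic model fitted on the full outer-training split) built without it.
Observed error for the conformal predictor is the fraction of individuals
whose *true-class* p-value is at or below $\alpha$; for the logistic model
an individual is an error when its case probability exceeds $1 - \alpha$
despite being a control, or falls below $\alpha$ despite being a case (both
strict, exactly as the rule is conventionally written). Coverage is the
fraction of singleton predictions; coverage, the uncertain fraction and the
empty fraction always sum to one.

`stratified_metrics()` restricts AUC, PPV and NPV to the predicted subset:
AUC with a DeLong 95% CI (via pROC), PPV/NPV with exact binomial CIs (the
CI method for the proportions is a package choice; no established
convention exists). Degenerate subsets yield `NA` plus a reason code, never
a silent zero. `empirical_method()` implements the standard comparator —
top $x\%$ predicted case, bottom $x\%$ predicted control, coverage $2x\%$
by construction — so the two approaches can be compared at matched coverage.
`run_table1_experiment()` sweeps a grid of architectures and emits one row
of metrics per (heritability, polygenicity, prevalence) cell.

```{r pipeline, eval = FALSE}
cfg <- architecture_config(n_individuals = 4000, m_snps = 4000, seed = 1)
run <- mccp_simulation_run(cfg)
ggplot2::autoplot(run$curve)
preds <- attr(run$curve, "predictions")
stratified_metrics(prediction_region(preds, alpha = 0.05))
```

## Numerical and design choices

* **Ties in p-value counting** are inclusive ($\ge$), exactly as the
  counting rule is defined; equal nonconformity scores therefore raise the
  p-value, which is the conservative direction.
* **Default $\alpha$ grid** is 0.01–0.50 in steps of 0.01: the unit interval
  above 0.5 is uninformative for two-class regions, and clinical interest
  concentrates near 0.
* **Separation** in the underlying scorer (not just in the GWAS) falls back
  to a ridge-penalized logistic fit (penalty on slopes only) with a warning.
* **Determinism**: every random draw flows from the configuration seed;
  fold assignment, the discovery split and the simulator are bit-reproducible
  given it, and pipeline artifacts embed a config hash so mismatched inputs
  are detectable.
* **Problem sizes**: the packaged analyses use the default cohort
  (n = 10,000, m = 20,000) for the headline validity and performance runs,
  and 4,000–6,000-scale cohorts for the architecture-ordering comparisons;
  these sizes give per-class binomial noise small enough for 3-SD checks
  while staying desk-scale.

## Known limitations

* Averaged cross-conformal p-values are only empirically valid; the exact
  finite-sample guarantee belongs to the single-split (inductive) variant.
* Under a population-prevalence test sample, per-class validity itself
  bounds what PPV can reach at a given $\alpha$: roughly $\alpha \cdot
  (1-K) \cdot n$ controls enter the case region, while predicted cases can
  never exceed $K \cdot n$. At $K = 0.05$ and $\alpha = 0.05$ this caps PPV
  near 0.5 even for a near-perfect PRS, and published per-cell figures
  obtained under other sampling designs are not directly comparable.
  Absolute levels from this simulator are therefore read qualitatively
  (better architectures give higher AUC and coverage), not as forecasts for
  real cohorts.
* The underlying scorer is logistic regression only; other scorers
  (k-NN, random forests, SVMs) and continuous-trait conformal prediction are
  out of scope, as are LD-aware PRS weighting schemes.
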