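---
title: "Validating biobank phenotype definitions with effect-size regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating biobank phenotype definitions with effect-size regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minppv)
```

## The estimand

A candidate case definition built from biobank self-report or electronic
health records labels $N$ participants as cases. Suppose a fraction $\pi$
of them are true cases and the remaining $1-\pi$ carry control allele
frequencies (pure misclassification). At a risk locus with control
effect-allele frequency $p_0$ and true-case frequency $p_1$, the labelled
case set has frequency $\pi p_1 + (1-\pi) p_0$, so its log odds ratio
against controls is attenuated relative to the true-case log odds ratio —
almost exactly proportionally for weak effects:
$\beta_{\text{obs}} \approx \pi \, \beta_{\text{true}}$ (the relative
error of this linearisation is below 2% for odds ratios up to 2 at common
frequencies; it is exact as $\beta_{\text{true}} \to 0$).

Regressing candidate effect estimates $y_i$ on reference effects $x_i$
from a specialist-diagnosed cohort across a panel of established risk
variants therefore estimates $\pi$ — a lower bound on the positive
predictive value of the definition (minPPV), because milder-but-true cases
with reduced genetic liability attenuate effects the same way pure
misclassification does. The method cannot distinguish the two; that is why
the slope is read as a lower bound rather than a point estimate of PPV.

## The fit

`ivw_slope()` fits weighted least squares through the origin with weights
$w_i = 1/s_i^2$ from the candidate standard errors:

$$\hat b = \frac{\sum_i w_i x_i y_i}{\sum_i w_i x_i^2}, \qquad
\mathrm{SE}(\hat b) = \sqrt{\frac{\hat\phi}{\sum_i w_i x_i^2}}, \qquad
\hat\phi = \max\!\left(1, \frac{\sum_i w_i (y_i - \hat b x_i)^2}{n-1}\right).$$

Design choices, made where the design was genuinely open:

* **No intercept.** The estimand is an attenuation factor: a variant with
  zero true effect must show zero expected candidate effect under any
  amount of contamination. An intercept would absorb part of the
  attenuation signal with ~35 points.
* **Candidate-SE weights only, by default.** Reference cohorts are far
  larger than candidate biobank case sets, so $s_{x,i} \ll s_{y,i}$ and
  the regression-dilution contribution of reference noise is negligible.
  An optional `weights = "both"` mode iterates
  $w_i = 1/(s_{y,i}^2 + \hat b^2 s_{x,i}^2)$ for reference panels with
  non-trivial uncertainty.
* **Multiplicative overdispersion, clamped at 1.** Residual heterogeneity
  beyond the sampling weights (e.g. locus-specific attenuation) inflates
  the SE; the clamp never lets the SE fall below its fixed-weight value.
  This is standard inverse-variance-weighting practice and is what makes
  CIs for very small case sets wide enough to cross 1.
* **Normal quantiles** for symmetric CIs (`slope_ci()`), matching the
  ±1.96-SE style of the benchmark table; with ~35 variants the difference
  from a t interval is immaterial next to the overdispersion choice.

Degenerate inputs are classed errors: fewer than 2 pairs, all reference
effects zero, non-positive SEs.

## Harmonization

`harmonize()` pairs variants by identifier (the reference panel is a
curated list, so positional matching buys nothing), orients every
candidate effect to the reference effect allele (sign-flipping swapped
alleles, relabelling complementary-strand records), and drops variants
whose allele sets cannot be reconciled. Palindromic (A/T, C/G) variants
are dropped by default: with a panel of a few dozen loci, conservative
exclusion is safer than frequency-based strand inference, and the bundled
synthetic panels avoid palindromic pairs entirely so nothing is lost
there. Harmonization is idempotent and the sign-flip is an involution;
both are property-tested.

## The simulation validation

`run_validation_sim()` is the package's own check that the slope recovers
a known true-case fraction:

1. `locus_panel()` defines the truth: by default 35 independent loci —
   echoing the size of a curated psoriasis risk-variant panel — with
   control effect-allele frequencies evenly spaced on $[0.1, 0.5]$ and
   true odds ratios log-spaced on $[1.1, 2.0]$, spanning the common-variant
   effect sizes seen for inflammatory skin disease.
2. `simulate_cohort()` draws allele counts under Hardy–Weinberg:
   controls $\sim \mathrm{Bin}(2N_0, p_0)$ per locus, labelled cases
   $\sim \mathrm{Bin}(2N_1, \pi p_1 + (1-\pi)p_0)$. Loci are independent
   (no LD), matching the independence assumption of the IVW fit.
3. `estimate_log_or()` computes per-locus Woolf estimators
   $\ln(ad/bc)$ with SE $\sqrt{1/a+1/b+1/c+1/d}$, adding the
   Haldane–Anscombe 0.5 to all four cells of any locus containing a zero.
4. Each replicate is harmonized and fitted; replicate $r$ uses seed
   $\texttt{seed} + r$, so any replicate reproduces in isolation.

At 200 replicates of 20,000 cases vs 20,000 controls the mean slope sits
within 0.03 of $\pi$ for $\pi \in \{0.4, 0.6, 0.8\}$ and the 95% CI covers
$\pi$ at close to nominal rate; the test suite runs exactly this
experiment. These sizes keep the full suite under a minute while leaving
Monte-Carlo error well inside the tolerances checked.

What the generator does **not** emulate: linkage disequilibrium between
panel variants, covariate or population-structure adjustment, genotyping
error, and the liability-threshold alternative in which contaminating
"cases" are mild true cases rather than non-cases. Passing tests therefore
show the estimator recovers $\pi$ under pure misclassification — not that
real biobank slopes decompose cleanly into misclassification versus
liability differences (they cannot; see "The estimand").

## Attenuated power

`analytic_power()` computes the power of the two-proportion test for a
risk factor of population frequency $p_2$ (default MAF 0.30) and true odds
ratio $\mathrm{OR}$ (default 1.1), attenuated by a definition's minPPV:
$\mathrm{OR}_{\text{eff}} = \exp(\text{minPPV} \cdot \ln \mathrm{OR})$,
case frequency $p_1 = p_2\mathrm{OR}_{\text{eff}} /
(1 - p_2 + p_2\mathrm{OR}_{\text{eff}})$, noncentrality

$$\lambda = \frac{(p_1 - p_2)^2}
{\bar p (1-\bar p)\left(\tfrac{1}{N_1} + \tfrac{1}{N_0}\right)},$$

with $\bar p$ the count-weighted pooled frequency, and power
$P\{\chi^2_1(\lambda) > \chi^2_{1,1-\alpha}\}$. Three choices matter:

* **Per-participant denominators.** The model counts risk-factor carriage
  per participant. Its Monte-Carlo oracle (`mc_power()`) simulates the
  same experiment — one exposure draw per participant — and applies the
  Woolf chi-square; the two agree within Monte-Carlo error across a grid
  of case counts and minPPV values (property-tested).
* **Nominal $\alpha = 0.05$, two-sided**, not genome-wide $5\times10^{-8}$:
  the benchmark power column is defined at the nominal threshold, read as
  per-variant power contributed to a larger meta-analysis.
* **Point-estimate attenuation.** The minPPV point estimate (not a CI
  bound) shrinks the effect; propagating slope uncertainty into power is
  out of scope.

Recomputing the 27-row benchmark from its published case counts and
slopes reproduces the published power column within ±0.015 everywhere
(tested at ±0.02); the residual discrepancy is consistent with the
original computation differing in pooled-vs-unpooled variance or
continuity handling, details that are not published. At minPPV = 0 the
noncentrality vanishes and power equals $\alpha$ exactly — a useful
calibration check that the suite asserts.

## Composite phenotype rules

`composite_rule()` expresses every benchmark definition as "at least $k$
of $n$ named component predicates" over a per-participant indicator table:
self-report (SRP), self-reported relevant medication (SRM, with SRPM =
SRP AND SRM), hospital main/secondary diagnosis (HESmain/HESsec/HESany),
thresholded GP diagnosis counts (GP/GP2/GP3 as $\ge 1/2/3$), and
psoriatic-arthritis-augmented variants that OR the PsA code into the
corresponding source. Case sets nest monotonically in $k$ and in the GP
threshold, and PsA augmentation can only grow a case set — all
property-tested against an exhaustive 8-participant truth table.

Controls default to participants with **no** psoriasis or PsA indicator
at all, guaranteeing case/control disjointness for every built-in rule.
The published control-selection criteria are not fully specified, so this
conservative default is a package choice and is configurable via the
`exclusion` argument.

`simulate_indicators()` generates synthetic indicator tables: a small
fraction of participants (default 3%) carry a psoriasis signal and each
source fires independently given that signal. It exists to exercise rule
logic, not to reproduce real between-source correlation structure.

## Problem sizes and determinism

The default experiment sizes — 35 loci, 200 validation replicates at
20,000/20,000, 2,000 Monte-Carlo power replicates — were chosen so that
Monte-Carlo standard errors are several-fold smaller than every tolerance
asserted, and the whole suite still runs in well under a minute. All
randomness flows through explicit integer seeds (`withr::with_seed`), so
count tables are bit-identical across runs; the validation experiment
derives per-replicate substreams as `seed + rep`.

## Limitations

* The slope conflates misclassification with genuinely lower genetic
  liability; it is a lower bound on PPV, not a misclassification rate.
* With ~35 loci the overdispersion estimate is noisy; the clamp at 1
  protects against anti-conservative SEs but not against locus-specific
  attenuation biasing the slope itself.
* Palindromic variants are discarded rather than frequency-resolved;
  panels dominated by A/T or C/G variants would lose precision.
* The power model is single-variant and covariate-free.
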