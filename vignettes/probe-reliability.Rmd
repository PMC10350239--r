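---
title: "Estimating probe reliability from duplicate methylation measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating probe reliability from duplicate methylation measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrel)
```

## The problem

Illumina methylation arrays report, per CpG probe, a beta value in [0, 1]:
the fraction of methylated signal. When the same blood sample is measured
twice — a technical duplicate, ideally on two different plates — the two
beta values rarely coincide, and the size of that disagreement varies
enormously across the hundreds of thousands of probes on an array. Probes
that cannot reproduce their own measurement contaminate association studies
with noise; a per-probe reliability estimate lets analysts filter or
down-weight them.

## The model

`methrel` treats each probe's duplicate data as a two-way crossed layout:
subject (random), replicate (random), no interaction. Writing $y_{ij}$ for
the beta value of subject $i$ in replicate $j \in \{1, 2\}$:

$$y_{ij} = \mu + b_i + r_j + e_{ij}, \qquad
  b_i \sim N(0, \sigma_b^2), \quad e_{ij} \sim N(0, \sigma_w^2),$$

with $\sigma_b^2$ the between-subject and $\sigma_w^2$ the within-subject
(technical) variance. Reliability is the between-subject share of total
variance, $\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$, estimated by the
single-measure, absolute-agreement, two-way random-effects intraclass
correlation computed from the ANOVA mean squares:

$$\widehat{ICC}(A,1) =
  \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)},
  \qquad k = 2.$$

The *absolute agreement* form keeps the replicate (column) mean square in
the denominator, so a systematic shift between replicates — a plate
effect — lowers the estimate even though it leaves the subject ranking
intact. Negative estimates are retained rather than clamped: they are
legitimate outcomes of the estimator for probes with essentially no subject
signal, and clamping would bias summaries of the reliability distribution.

### Why a modified ICC

The ICC is a variance ratio, so a probe with unusually large
between-subject variance can score highly even when its duplicates differ
by a visible fraction of the measurement scale. To penalise absolute
disagreement, the package computes the Bland–Altman limits of agreement of
the paired differences $d_i = y_{i1} - y_{i2}$,
$\bar d \pm z \, \sigma_d$ with $z = 1.96$, calls $z\,\sigma_d$ the
half-width of the limits of agreement (HoLA), and defines

$$mICC = ICC - HoLA.$$

HoLA is on the beta scale, so mICC deliberately mixes a dimensionless ratio
with a scale-dependent penalty; that is the point — two probes with equal
ICC but different absolute disagreement should not be ranked equally. Both
statistics are classified with the conventional bands Poor / Fair / Good /
Excellent.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `z` | 1.96 | limits-of-agreement multiplier (95% normal interval); unitless |
| `cutpoints` | 0.4, 0.6, 0.75 | class boundaries for ICC and mICC alike |
| `max_missing_frac` | 0.05 | probes missing in more than 5% of samples are dropped |
| `min_pairs` | 3 | fewer complete pairs than this gives missing statistics |
| `require_cross_plate` | `FALSE` | keep only subjects whose duplicates sit on different plates |
| `seed` | 1 | controls the random replicate selection behind `sd_beta` |

Boundary convention: the published class bands are ambiguous at their
edges (the Fair and Good bands share the value 0.6, and nothing is said
about 0.4 and 0.75). The package fixes Poor: $v < 0.4$; Fair:
$0.4 \le v < 0.6$; Good: $0.6 \le v \le 0.75$; Excellent: $v > 0.75$, and
exposes the per-cutpoint rule in `classification_scheme()` so the choice is
auditable and changeable. mICC uses the same cutpoints as ICC.

`require_cross_plate` defaults to off because general users may lack plate
metadata, although a cross-plate design is what the statistics are meant to
describe; same-plate duplicates understate the technical variance a
real study would face.

The per-probe `sd_beta` is computed after selecting one duplicate per
subject uniformly at random (using both would double-count subjects and
understate spread); the selection seed is recorded in the fit object so the
output is reproducible.

## Numerical choices and degenerate inputs

* Mean squares come from the closed-form sums-of-squares decomposition;
  the residual sum of squares is truncated at zero to absorb floating-point
  cancellation. A vectorised row-wise implementation handles whole
  matrices; the test suite asserts probe-by-probe equality with the scalar
  functions and with a brute-force oracle to 1e−10.
* $\sigma_d$ uses the sample standard deviation (n − 1 denominator).
* A probe with zero total variation has an undefined ICC (0/0); it is
  reported as missing with class "Undefined" and excluded from summaries,
  as are probes below `min_pairs`. Pairs with either replicate missing are
  dropped per probe (pairwise-complete) and the retained count is recorded
  in `n_pairs`.
* Computations run on whatever scale is supplied; beta values are the
  documented default, and `read_beta_matrix(range_check = FALSE)` admits
  M-values or other unbounded scales.
* The rank-sum group contrast (`compare_groups`) uses exact enumeration of
  all assignments (valid under ties) when both groups have at most 10
  members, and the tie-corrected normal approximation otherwise. The exact
  path is enumerated directly because the standard test function offers no
  exact mode in the presence of ties.
* Group contrasts across probe annotations are a deliberate
  simplification: probes are correlated along the genome, and a rank-sum
  p-value that treats probes as independent will overstate significance.
  Mixed models with genomic random effects are out of scope; treat these
  p-values as descriptive.

## The synthetic generator

`synthetic_truth()` / `simulate_duplicates()` generate

$$y_{pij} = \mathrm{clip}(\mu_p + b_{pi} + s_p \cdot 1[j = 2] + e_{pij},
  \ \varepsilon, 1 - \varepsilon), \qquad \varepsilon = 10^{-6},$$

a Gaussian model on the beta scale with an optional plate shift $s_p$
added to replicate 2, clipped to the unit interval. Defaults are one
choice of realistic study conditions: 69 subjects (a typical duplicate
cohort), probe means spread over [0.1, 0.9], $\sigma_b^2 = 0.01$ and
$\sigma_w^2 = 0.0025$ — between-subject SD 0.1 and technical SD 0.05,
values typical of a variable CpG, giving a true ICC of 0.8 with negligible
clipping. The generator warns when parameters force more than half of a
probe's values onto the boundary, where the nominal variance components no
longer hold.

What the generator emulates: duplicate designs with known
$\sigma_b^2/\sigma_w^2$, plate shifts, boundary compression of
near-0/near-1 probes, missingness injected by the caller. What it does not
emulate: the skewed, bimodal marginal distribution of real beta values,
probe-type chemistry differences, spatially correlated array artifacts,
co-methylation between neighbouring probes, and cell-composition
variation. Passing parameter-recovery tests therefore shows the estimators
are correct under the stated model, not that real arrays satisfy that
model.

A Gaussian-on-beta-scale model with clipping was chosen over a logit-scale
model for transparency: the generating variance components are exactly the
quantities the estimators target, so recovery tests have closed-form truth.
The clipping caveat is the price, and tests keep their means away from the
boundaries except where boundary behaviour is itself under test. The plate
shift is additive on replicate 2 only — the simplest mechanism that
reproduces the observed direction of plate effects on absolute-agreement
ICC.

## Validation design and problem sizes

The test suite checks, among others:

* brute-force oracle equivalence of the ICC estimator on 1000 random small
  duplicate sets (and a second independent route through `stats::aov`);
* parameter recovery at 200 probes × 500 subjects with
  $\sigma_b^2 = 0.04$, $\sigma_w^2 = 0.01$: mean ICC within ±0.02 of 0.8
  and mean HoLA within 5% of $1.96\sqrt{2 \cdot 0.01} \approx 0.277$;
* invariance properties: replicate-label swap; global location/scale
  behaviour (ICC invariant, HoLA scales); classification monotonicity;
* direction properties: a plate shift of 0.05 at
  $\sigma_b^2 = 0.02, \sigma_w^2 = 0.005$ lowers the mean ICC; probe means
  near the boundaries depress ICC relative to mid-range means.

One caution discovered during validation: "adding a constant to one
replicate lowers the absolute-agreement ICC" is **not** universally true.
If the columns were already biased in the opposite direction the shift can
cancel the existing discrepancy, and for probes with a negative ICC
numerator an inflated denominator moves the estimate toward zero, i.e.
upward. The direction holds — and is tested — for probes with genuine
subject signal and a shift that enlarges the observed replicate
discrepancy, which is the configuration the plate-effect claim is about.

## Known limitations

* Exactly two replicates per subject; subjects listed with more are
  excluded rather than down-sampled.
* mICC mixes scales by construction; comparisons of mICC across
  measurement scales (beta vs M-values) are not meaningful, while ICC
  comparisons are.
* The classification boundary convention at 0.4 / 0.6 / 0.75 is a fixed
  editorial choice; values exactly on a boundary are rare but the
  convention matters for reproducing published class counts.
* Reliability estimated from 69 pairs carries substantial sampling noise
  per probe; cross-study Spearman correlations of ~0.7 between independent
  reliability tables are expected, not a defect.
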