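---
title: "Tumor content chart-assisted HER2/CEP17 digital PCR analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor content chart-assisted HER2/CEP17 digital PCR analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcchart)
```

# The problem

*HER2* amplification status guides anti-HER2 therapy in advanced gastric
cancer, and it must usually be established on a small formalin-fixed biopsy.
The standard readouts — immunohistochemistry (IHC) and in situ hybridization
(ISH) — are either poorly reproducible in the equivocal middle of their scale
or costly and slow. Digital PCR offers a cheap, robust alternative: it
measures the bulk *HER2*/CEP17 copy-number ratio of the extracted DNA. But a
biopsy is a mixture of cancer cells and diploid stroma, so the bulk ratio
understates the per-cell amplification in proportion to the stromal
fraction. `tcchart` implements a closed-form correction for that dilution:
the Tumor Content (TC) chart.

# Partition statistics

A digital array splits template DNA over $N$ chambers (770 per panel).
With molecules landing independently, the number per chamber is Poisson
with mean $\lambda$, a chamber is positive iff it received at least one
molecule, and the positive count is $k \sim \mathrm{Binomial}(N,
1 - e^{-\lambda})$. Inverting the occupancy probability gives the maximum
likelihood estimate

$$\hat\lambda = -\ln\!\left(1 - k/N\right),$$

implemented in `poisson_lambda()`. The delta method gives
$\mathrm{Var}(\hat\lambda) \approx p / (N(1-p))$ with $p = k/N$; `tcchart`
reports a Wald interval on the $\lambda$ scale, and intervals for the
target/reference ratio $r = \hat\lambda_T/\hat\lambda_R$ by the delta
method on $\log r$. These are the standard cheap approximations; they are
accurate at $N = 770$ (simulated coverage 93–97% across
$\lambda \in [0.1, 1.8]$, checked in the test suite) and exact methods are
deliberately out of scope. A saturated panel ($k = N$) is an error, never a
capped value — capping would silently bias $r$ downward. Multi-panel runs
are pooled by summing $k$ and $N$ before a single correction; at equal
loading the chambers are exchangeable, and pooling is the efficient
estimator. (The pooled-count variance term $N(N-k)$ is computed in double
precision: at $N = 77{,}000$ it overflows 32-bit integer arithmetic.)

```{r}
dpcr_ratio(panel_count(383, 770), panel_count(398, 770))
```

# The mixture model

Let $x \in [0,1]$ be the tumor content ratio (TCR): the fraction of
nucleated cells that are cancerous. Assume cancer cells are homogeneous
with $A$ copies of the CEP17 reference locus and $B$ copies of *HER2* per
cell, and stromal cells are diploid (2 copies of each). The bulk ratio is
then

$$r = \frac{Bx + 2(1 - x)}{Ax + 2(1 - x)},$$

implemented in `forward_ratio()`. At $x = 0$, $r = 1$ for any copy numbers;
at $x = 1$, $r = B/A$.

Amplification is defined per cell as $B/A \ge 2$. The condition $B/A < 2$
is algebraically equivalent to

$$r < 2 - \frac{2(1 - x)}{(A - 2)x + 2},$$

the $B/A = 2$ iso-curve at CEP17 copy number $A$ (`boundary_ratio()`). The
curve is non-decreasing in $A$, so bracketing the unknown $A$ by
$[a_{\min}, a_{\max}]$ brackets the decision: below the curve at $a_{\min}$
the specimen is non-amplified for *every* admissible $A$; at or above the
curve at $a_{\max}$ it is amplified for every admissible $A$; between them
the call genuinely depends on $A$ and the sample is *equivocal*. With the
defaults $a_{\min} = 2$, $a_{\max} = 8$ these boundaries reduce to
$r = x + 1$ and $r = (7x+1)/(3x+1)$. All curves pass exactly through
$(0, 1)$ and $(1, 2)$.

## Parameters and defaults

* `a_min = 2`, `a_max = 8` (copies/cell). Clinically observed CEP17 copy
  numbers in gastric cancer run about 2–6; 8 adds a safety margin. Both are
  exposed because a laboratory with its own aneusomy survey may justify a
  tighter bracket, which shrinks the equivocal band.
* `normal_copy` is fixed at 2 and *not* configurable: the boundary algebra
  hard-codes diploid stroma, and a different stromal ploidy would need a
  re-derivation, not a parameter change.
* `x_floor = 0.05`. As $x \to 0$ both boundaries collapse to $r = 1$, so
  any measured $r \ge 1$ would be called positive on the strength of
  essentially no tumor signal. Below the floor `tc_classify()` returns
  `UNDETERMINED` with a warning instead of a call. 0.05 is a pragmatic
  choice — at 5% tumor content the band $[1.05, 1.26]$ is already narrow
  relative to measurement error — and a laboratory may raise it.

## Numerical choices

The equivocal band is half-open, $x + 1 \le r < (7x+1)/(3x+1)$, with ties
going to the less-negative category. Boundary comparisons carry a relative
tolerance of $10^{-9}$: a point constructed algebraically *on* a boundary
(say $B/A$ exactly 2 at $A = 2$, where $r = x + 1$ identically) can
evaluate one ulp below it in floating point, and without the tolerance the
model's central guarantee — a truth with $B/A \ge 2$ is never called
NEGATIVE — fails on such ties. The tolerance is far below measurement
precision (ratios are reported to 2 decimals), so it cannot affect a real
call.

## Inversion

When DISH supplies the per-cell CEP17 count ($A$ = average CEP17
signals/cell over 20 nuclei), the mixture model inverts in closed form:

$$\frac{B}{A} = r + \frac{2(r - 1)(1 - x)}{Ax},$$

(`estimate_ba_ratio()`), the exact algebraic inverse of the forward model —
the test suite checks the round trip to $10^{-9}$ over $10^4$ random
parameter points. Where clustered *HER2* signals defeat direct counting,
the pure-tumor convention $B' = rA$ (`estimate_b_prime()`) gives the
implied per-cell *HER2* copy number, and `fit_b_prime_series()` extends it
to a least-squares fit over a dilution series via the linearization
$r(Ax + 2(1-x)) = Bx + 2(1-x)$.

```{r}
estimate_ba_ratio(r = 28.25, x = 0.414, A = 3.2)
estimate_b_prime(r = 5.69, A = 4.15)
```

# DISH scoring and IHC

`dish_metrics()` turns total signal counts over $n$ scored nuclei
(default 20) into the ratio and per-cell averages; `classify_dish()` applies
the ASCO/CAP-derived rules — positive if ratio $\ge 2.0$ *or* average
*HER2* $\ge 6.0$ signals/cell (the "and/or" is implemented as inclusive-or,
which is what makes a ratio-negative but signal-rich case positive);
equivocal if the average is in $[4.0, 6.0)$; negative otherwise. Thresholds
always see full-precision values; rounding is presentation-only.
Uncountable *HER2* clusters are capped at 7/14/21 signals by size class
(`her2_cluster_total()`), matching scoring convention. IHC scores are
carried as the four-level Dako scale and cross-tabulated against TC-chart
areas by `concordance_table()`.

# Tumor content estimation

TCR is a nucleus-count fraction: cancerous nuclei over all nucleated cells
in the region matched to the DNA extraction (`tcr_from_counts()`). The
production image-analysis step is proprietary software; `classify_nuclei()`
stands in with the feature those pipelines discriminate on — nucleus size,
enlarged in cancer — thresholded manually or by Otsu's two-class variance
criterion (deterministic and assumption-light). This is a faithful stand-in
for tabulated nucleus features, not a segmentation tool: it starts from a
size table, never from an image, and a multimodal or poorly separated size
distribution will defeat the automatic threshold (the suite demonstrates
recovery only at $\ge 6$-sd separation).

# The simulator: what it emulates, and what it does not

`simulate_panel()` draws chamber counts under the standard occupancy model:
expected concentrations $\lambda_R = m(Ax + 2(1-x))$,
$\lambda_T = m(Bx + 2(1-x))$ for loading density $m$ (genome
equivalents/chamber), counts $\sim \mathrm{Binomial}(N n_{\text{panels}},
1 - e^{-\lambda})$, one global seed, no hidden entropy. The default
$m = 0.25$ puts diploid reference occupancy at $\lambda = 0.5$, inside the
0–1 molecules/chamber regime arrays are run in and matching the magnitudes
seen on real 770-chamber panels ($\lambda \approx 0.3$–$1.8$); loading
densities are otherwise unreported for real runs, so this is a stated-world
choice made once. `mixture_series()` mirrors the bench validation in which
tumor-line DNA is mixed stepwise with diploid LCL DNA at volume ratios
8:2 … 1:9, treating DNA mass fraction as $x$. That convention is a known
approximation — aneuploid genomes weigh more per cell, so mass fraction and
cell fraction differ — adopted because it is how the bench series is
plotted.

Not modeled: pipetting error, chamber-volume variability, amplification
efficiency, probe dropout, per-cell heterogeneity of the tumor compartment.
A green simulation test therefore establishes the statistical behavior of
the estimator chain under the stated model, not robustness to assay
artifacts.

# Design choices that were genuinely open

* **Pooling vs averaging panels.** Summing $k$ and $N$ then correcting once
  was chosen over averaging per-panel $\hat\lambda$s: chambers are
  exchangeable at equal loading and pooling has strictly smaller variance.
  Per-panel estimates remain available by quantifying panels individually.
* **What the printed example ratios cannot settle.** One published
  cell-line ratio prints as 2.14 where the closed form over its printed
  counts gives 2.130; whether extra panels or different rounding produced
  the extra 0.01 is unknowable. The implementation reports what it
  computes.
* **Direct-ratio input.** Sample sheets may carry a measured `r` directly,
  because published per-case chamber counts are generally not available;
  this is what lets the bundled biopsy dataset reproduce the published
  per-cell estimates and areas.
* **Chart axis.** The chart keeps the diagnostically dense band readable
  with a vertical axis linear up to $r = 2.5$ and logarithmic above, the
  two pieces joined with a continuous first derivative. The break placement
  is cosmetic and configurable.

# Limitations

The model assumes a homogeneous tumor compartment and exactly diploid
stroma; intratumoral heterogeneity shows up only as an averaged $r$ and can
park a genuinely mixed lesion in the equivocal band. TCR is taken at face
value from a serial section and any mismatch between the imaged region and
the DNA-extracted region propagates directly into the call. Below
`x_floor` no call is attempted at all. The classifier bracket is only as
good as the assumed CEP17 range: a monosomic tumor ($A < 2$) is outside the
derivation's domain.
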