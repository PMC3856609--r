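---
title: "Minimized-FDR significance calling: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimized-FDR significance calling: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifdr)
```

## The problem

A two-group feature screen (a microarray or RNA-seq experiment comparing
treated against control samples) tests tens of thousands of features at
once. The practical question is never "is this one feature significant" but
"how large a call set can I take downstream while keeping the expected
fraction of false calls — the false discovery rate (FDR) — under control".
Under the Bayesian mixture view, the FDR of a rejection region $\Gamma$ is

$$\mathrm{FDR}(\Gamma) = P(H = 0 \mid d \in \Gamma)
  = \frac{\pi_0\, P(d \in \Gamma \mid H = 0)}{P(d \in \Gamma)},$$

where $\pi_0$ is the proportion of truly null features. p-value based
procedures (Benjamini–Hochberg step-up, Storey q-values) estimate
$P(d \in \Gamma \mid H=0)$ from a parametric null for a per-feature test
statistic. This package instead follows the nonparametric permutation route:
the null is built by recomputing the statistic under random relabelings of
the samples, which keeps the estimate honest when the parametric assumptions
fail (skewed, bounded or heteroskedastic data).

## The moderated d-statistic

For feature $i$, with groups $X$ (the first group encountered in the labels,
$N_X$ samples) and $Y$ ($N_Y$ samples), the statistic is a difference score
over a damped spread,

$$d_i = \frac{r_i}{s_i + s_0}.$$

Two forms are provided:

* **t form** — $r_i = \bar X_i - \bar Y_i$ and $s_i$ is the pooled standard
  error $\sqrt{\left[\sum_X (x-\bar X_i)^2 + \sum_Y (y-\bar Y_i)^2\right]
  (1/N_X + 1/N_Y)/(N_X+N_Y-2)}$, so $r_i/s_i$ is the classical equal-variance
  t statistic.
* **ranksum form** — $r_i$ is the Wilcoxon rank sum of group $X$ centred at
  its null mean, and $s_i = \sqrt{N_X N_Y (N_X+N_Y+1)/12}$ is its null
  standard deviation, identical across features. We take the square root of
  the classical variance expression so that $r/s$ is a z-like score on the
  same footing as the t form; ties get average ranks.

The fudge factor $s_0 \ge 0$ is shared across features and guards against
the instability of $s_i$ at small sample sizes: features with tiny spread
estimates cannot blow up into huge scores. `select_s0()` follows the SAM
recipe: features are binned into up to 100 equal-count bins by their spread
rank, the median absolute deviation of $d$ is computed per bin for each
candidate $s_0$, and the candidate minimizing the coefficient of variation
of those bin MADs wins — i.e. the dispersion of $d$ is made as independent
of the spread level as possible. Candidates are the type-1 quantiles of
$\{s_i\}$ at probabilities $0, 0.05, \dots, 1$ (actual members of the spread
pool) plus $0$; scanning every distinct spread value instead is supported
via the `candidates` argument but costs $O(M^2)$ and changes results only
marginally, so the percentile grid is the default. Ties are broken towards
the smaller candidate, which also resolves the degenerate case where the
criterion is flat (for instance when all spreads are equal). If every
spread is zero while some difference score is not, there is no valid
statistic and the function refuses rather than divide by zero.

## The permutation null

`permutation_null()` draws `B` relabelings of the samples that preserve the
two group sizes and recomputes $(r, s)$ — hence $d$ — under each, reusing
the $s_0$ selected on the observed labelling so that observed and permuted
scores share a scale. With $W$ samples and $\binom{W}{N_X}$ distinct
labelings, the scheme is: enumerate all of them when there are at most `B`;
sample distinct labelings without replacement when there are at most
`10 B`; otherwise sample uniformly with replacement. Small designs are
therefore handled exactly and large ones stochastically, all reproducible
from the single `seed` argument.

Two derived quantities matter downstream:

* the **expected order statistics** $E[\hat d^*_i]$ — each permutation's
  d-values sorted ascending, averaged column-wise — which drive the
  Δ-threshold baseline, and
* the **null proportion** $\hat\pi_0$, estimated Storey-style from the
  central window of the pooled permuted values:
  $\hat\pi_0 = \min\!\big(1, \#\{q_{25} \le d_i \le q_{75}\}/(0.5M)\big)$
  with type-7 (linearly interpolated) quantiles. The window is exposed as a
  parameter (`window = c(0.25, 0.75)`) since reasonable implementations
  differ; a zero estimate is floored at $1/M$ because $\hat\pi_0 = 0$ would
  collapse every downstream FDR estimate to zero.

## Estimating the FDR of an asymmetric region

A rejection region is a pair of cut-offs,
$\Gamma(\tau^+, \tau^-) = \{d : d > \tau^+ \text{ or } d < \tau^-\}$, open
at both boundaries. Calling the $N^+$ largest and $N^-$ smallest observed
d-values places $\tau^+$ at the $(N^+\!+1)$-th largest and $\tau^-$ at the
$(N^-\!+1)$-th smallest observed order statistic (an infinite sentinel when
a side takes every feature). The estimate is

$$\widehat{\mathrm{FDR}} = \min\!\left(1,\;
  \frac{\mathrm{median}_b\{FP^+_b + FP^-_b\}\,\cdot\,\hat\pi_0}
       {TP^+ + TP^-}\right),$$

with $FP^\pm_b$ the strict exceedance counts of permutation $b$ and
$TP^\pm$ those of the observed values themselves. Numerical conventions,
all of which matter for exact reproducibility: boundaries are strict, so
observed duplicates of a cut-off value are not called and realized call
counts can fall short of the nominal $(N^+, N^-)$ under ties; the median
for even `B` is the midpoint of the central pair; ties in the observed
sort are broken by feature index; the denominator uses the realized
exceedance counts (identical to $N^+ + N^-$ for distinct values); a region
containing no observed value has no defined FDR and is skipped rather than
scored.

## Minimizing FDR over splits, and the maximum call set

The key observation is that at a fixed total call count $N$ there are
$N + 1$ ways to split the region, $(0, N), (1, N-1), \dots, (N, 0)$, and
the estimated FDR is not symmetric in the split: the cheapest region is
often lopsided. A Δ-threshold selector cannot reach most of these splits
(see below), so the package searches them directly:

* `minimize_fdr_at_n()` scores all $N+1$ splits and returns the minimizer
  (ties go to the smaller positive count, making the result deterministic).
  It is a literal scan, optimal at its $N$ by construction.
* `max_features()` finds the largest $N$ whose minimized estimate falls
  strictly below the cut-off $\Psi$. Because the minimized estimate at each
  $N$ bounds every split's estimate from below, the first qualifying $N$
  found scanning downward from the cap $M_\rho$ is the global maximum —
  no selection that calls the $n$ largest/smallest features can beat it.
  No monotonicity of the minimized estimate in $N$ is assumed; the scan is
  downward with an early exit precisely because the curve need not be
  monotone.

A naive implementation costs $O(M_\rho^2 \cdot M \cdot B)$. The package
instead precomputes, once, the one-sided counts
$TP^\pm_k$ and $FP^\pm_{k,b}$ for $k = 0..M_\rho$
(`precompute_counts()`, two `findInterval()` passes per permutation over
its sorted row); any split's false-positive vector is then the sum of two
precomputed rows and costs $O(B)$ via a selection algorithm for the median.
The split scan itself is compiled code, so the whole search is
$O(M_\rho M B + M_\rho^2 B)$. $M_\rho$ defaults to 1000, clipped to $M$,
and is a plain argument — an automatic bound is possible in principle but
is out of scope here.

## Baselines

* **BH** (`bh_select()`): classical step-up via `stats::p.adjust`, with
  pooled-variance two-sided t p-values by default; rank-sum p-values use
  the tie-corrected normal approximation without continuity correction.
* **Storey** (`storey_select()`): fixed-λ estimator
  $\hat\pi_0 = \#\{p_i > \lambda\}/((1-\lambda)M)$ (default λ = 0.5,
  floored at $1/M$), q-values by the cumulative-minimum construction. With
  $\hat\pi_0 = 1$ it reduces exactly to BH, which the tests assert.
* **Δ-threshold SAM** (`sam_delta_select()`, `sam_max_features()`): with
  features sorted by $d$, $\Delta_i = d^*_i - E[\hat d^*_i]$; the positive
  cut-off is the first positive-side feature (ascending) with
  $\Delta_i \ge \Delta_0$, the negative cut-off the first negative-side
  feature (descending) with $\Delta_i \le -\Delta_0$. Because Δ need not be
  monotone in $d$ — one outlying permuted column is enough — a tiny change
  in $\Delta_0$ can jump the implied call count discontinuously, and whole
  groups of features can only be called all-or-nothing. That is exactly the
  limitation the split search removes. `sam_max_features()` scans a grid of
  thresholds (default: 100 log-spaced points over the positive |Δ| range)
  and keeps the largest qualifying call set. Each selected region is scored
  through the same FDR functional the split search minimizes — in
  particular, a side that selects no features is cut at the extreme
  observed order statistic rather than at infinity. This keeps the two
  methods on one scale and makes the dominance guarantee (the Δ-grid can
  never call more than the split search at the same $\Psi$) an exact
  inequality, which the test suite asserts instance by instance.

## The synthetic benchmark

`benchmark_scenario()` builds the package's reference simulation: 10400
features × 16 samples (8 per group), 10000 nulls (5000 standard normal,
5000 uniform on $[-3, 3]$ in both groups) and 400 alternatives in four
categories — 50 × N(0,1) vs N(−2,1), 150 × N(0,1) vs N(1,1),
150 × U[−3,3] vs U[−2,4], 50 × U[−3,3] vs U[−1.5,4.5]. Every draw is
independent across features and samples; `run_study()` runs replicate
datasets (per-replicate seed = `base_seed` + replicate index), records each
method's calls at the estimated-FDR cut-off and its estimated/true FDR
versus call count curves, and averages curves across replicates aligned on
the call count. The default study size in the package's tests is 200
replicates at `B = 100`, which keeps the whole suite in the minutes range
while pinning the Monte-Carlo error of mean call counts well below one
feature.

What the generator emulates: a heavy-tailed mixture of null families (half
of them non-Gaussian, where t p-values are miscalibrated in the far tail),
weak-to-moderate shift alternatives in both directions, and the
feature-independence that permutation tests assume. What it does not
emulate: correlation between features (co-regulated genes), intensity-
dependent variance, missing values, or outlier samples. Passing tests on
this generator therefore demonstrate the estimator's internal correctness
and calibration under independence, not robustness to correlated real
data.

Two empirical properties of this benchmark regime, both computed by the
test suite, are worth stating plainly. First, the effect sizes are small
relative to 8-samples-per-group noise: at the 0.05 cut-off the permutation
methods call only a handful of features per replicate, and the realized
(truth-known) FDR of a ~20-feature call set is far above 0.05 — there is
simply no large call set with a small true FDR in this data, and the
permutation estimate reflects that honestly. Second, in this same far-tail
regime the two-sided-t step-up baselines call *more* features than the
permutation methods while exceeding their nominal FDR on the bounded
uniform nulls — the parametric miscalibration the permutation route
exists to avoid. The split search still dominates the Δ search replicate
by replicate, its averaged true-FDR curve stays below its averaged
estimated-FDR curve, and pure-null data yields $\hat\pi_0 \approx 1$ and
essentially no calls.

## Degenerate inputs and edge policies

* Zero-variance features: $r = 0, s = 0$ gives $d = 0$ when $s_0 > 0$; an
  all-zero-spread dataset with nonzero differences is an error. Degenerate
  t features (no variance, no difference) get p = 1 — no evidence.
* `estimate_fdr` refuses an empty region ($N^+ + N^- = 0$) and a region
  containing no observed values (possible under ties); the split scans skip
  such splits instead of scoring them.
* $\hat\pi_0$ is clipped to $(0, 1]$ with floor $1/M$.
* All randomness (simulation draws, relabelings) flows from explicit seed
  arguments through a save/restore of the RNG state, so library calls never
  perturb a caller's random stream.

## Limitations

Only two-class unpaired designs are supported — no paired, multi-class or
survival statistics, and no missing-data handling. The permutation count
`B = 100` (default) bounds the resolution of the per-permutation
false-positive median; very small tail probabilities are quantized
accordingly. The Δ-baseline's grid approximates a continuum of thresholds;
a qualifying threshold between grid points can be missed, which only makes
the reported dominance conservative. Feature correlation violates the
exchangeability the permutation null assumes and is not modelled here.
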