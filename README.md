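# mifdr

Permutation-based false discovery rate (FDR) control for two-group,
feature-by-sample screens — microarray or RNA-seq style differential
expression with tens of thousands of features and a handful of samples per
group.

## The method

Each feature gets a moderated score `d = r / (s + s0)`: a difference score
`r` (difference of group means, or a centred Wilcoxon rank sum) over its
spread `s` damped by a shared fudge factor `s0` chosen so the dispersion of
`d` is independent of the spread level. The null distribution of `d` is
built nonparametrically from `B` random relabelings of the samples, and the
FDR of an asymmetric rejection region
`Γ(τ⁺, τ⁻) = {d > τ⁺} ∪ {d < τ⁻}` is estimated as

```
FDR(N⁺, N⁻) = min(1, median_b{FP⁺_b + FP⁻_b} · π̂0 / (TP⁺ + TP⁻))
```

with `FP±_b` the permuted exceedance counts beyond the cut-offs and `π̂0`
the Storey-style null-proportion estimate from the pooled permuted values.

The package's core idea: calling `N` features leaves `N + 1` choices of how
to split them into `N⁺` positive and `N⁻` negative calls, and the estimated
FDR can differ a lot across splits. So it

* **minimizes FDR at fixed N** by scoring every split
  (`minimize_fdr_at_n()`), and
* **maximizes N under an FDR cut-off Ψ** (`max_features()`): scan total
  call counts downward from a cap `M_ρ`; at each count minimize over
  splits using precomputed one-sided false-positive tables; stop at the
  first count whose minimized estimate is below Ψ. Because the minimized
  estimate bounds every split, the result is provably the largest call set
  any order-statistic cut-off selection can reach — in particular it can
  never call fewer features than the SAM Δ-threshold selector at the same
  Ψ, an exact dominance the test suite asserts.

Baselines included for comparison: Benjamini–Hochberg step-up, Storey
q-values (both on t or rank-sum p-values) and the SAM Δ-threshold search,
plus a synthetic-data study harness (`run_study()`) with ground-truth FDR
tracking.

## Worked example

```r
library(mifdr)

# 1000 features x 16 samples: 950 nulls, 50 features shifted by 2.5 sd
sc <- simulation_scenario(
  data.frame(n_features = c(950L, 50L),
             dist1 = "normal", a1 = 0, b1 = 1,
             dist2 = "normal", a2 = c(0, 2.5), b2 = 1,
             alternative = c(FALSE, TRUE)),
  n_per_group = 8L)
sim <- simulate_dataset(sc, seed = 7)

fit <- mifdr(sim$dataset, statistic = "t", mode = "max_features",
             psi = 0.05, B = 100, seed = 42)
fit
#> <mifdr_fit> t statistic, s0=0.8302, B=100, pi0=0.986
#> <mifdr_result> N=50 calls (N+=0, N-=50), estimated FDR=0.03944

glance(fit)
#> # A tibble: 1 × 9
#>   n_called n_pos n_neg    fdr   pi0    s0     B statistic   psi
#>      <int> <int> <int>  <dbl> <dbl> <dbl> <int> <chr>     <dbl>
#> 1       50     0    50 0.0394 0.986 0.830   100 t          0.05

true_fdr(which(tidy(fit)$called), sim$truth)
#> [1] 0.02
```

The fit found the largest call set with estimated FDR below 0.05: all 50
calls on the negative side (the alternatives were up-shifted in group 2, so
`r = X̄ − Ȳ` is negative for them), estimated FDR 0.039 against a realized
(truth-known) FDR of 0.02 — the estimate bounds the truth from above.
`tidy(fit)` gives the per-feature table, `autoplot(fit)` the observed
versus expected order-statistic plot with calls highlighted, and
`write_results(as_result_table(fit), path)` a self-describing TSV.

For file-based use there is a thin command-line wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "mifdr.R", package = "mifdr"))') \
  call --matrix expr.tsv --labels labels.tsv --out results.tsv --psi 0.05
```

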