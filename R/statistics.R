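#' Difference score and spread for the t-form statistic
#'
#' For each feature, `r` is the difference of group means (X minus Y) and `s`
#' is the pooled standard error
#' \deqn{s_i = \sqrt{\left[\sum_{x \in X}(x-\bar X_i)^2 + \sum_{y \in Y}(y-\bar Y_i)^2\right]
#'   (1/N_X + 1/N_Y) / (N_X+N_Y-2)}}
#' so that `r/s` is the classical pooled-variance two-sample t statistic.
#'
#' @param dataset An [expression_dataset()]; both groups need >= 2 samples.
#' @return A list with numeric vectors `r` and `s` (length M).
#' @export
t_components <- function(dataset) {
  idx <- group_indices(dataset)
  nx <- length(idx$x); ny <- length(idx$y)
  if (nx < 2L || ny < 2L) stop_input("t statistic needs >= 2 samples per group")
  X <- dataset$values[, idx$x, drop = FALSE]
  Y <- dataset$values[, idx$y, drop = FALSE]
  mx <- rowMeans(X); my <- rowMeans(Y)
  ssx <- rowSums(X * X) - nx * mx * mx
  ssy <- rowSums(Y * Y) - ny * my * my
  # guard tiny negative round-off from the sum-of-squares shortcut
  ss <- pmax(ssx + ssy, 0)
  s <- sqrt(ss * (1 / nx + 1 / ny) / (nx + ny - 2))
  list(r = unname(mx - my), s = unname(s))
}

#' Difference score and spread for the ranksum-form statistic
#'
#' Measurements of each feature are pooled across the two groups and ranked
#' from lowest to highest (average ranks for ties). `r` is the Wilcoxon
#' rank-sum of group X centred at its null mean,
#' `r_i = sum of X ranks - N_X (N_X + N_Y + 1)/2`, and `s` is the null
#' standard deviation `sqrt(N_X N_Y (N_X+N_Y+1)/12)`, identical for every
#' feature. `r/s` is therefore a z-like score, rank-invariant under strictly
#' monotone per-feature transforms.
#'
#' @inheritParams t_components
#' @return A list with `r` (length M) and `s` (length M, all equal).
#' @export
ranksum_components <- function(dataset) {
  idx <- group_indices(dataset)
  nx <- length(idx$x); ny <- length(idx$y); n <- nx + ny
  ranks <- t(apply(dataset$values, 1L, rank))
  if (nrow(dataset$values) == 1L) ranks <- matrix(ranks, nrow = 1L)
  r <- rowSums(ranks[, idx$x, drop = FALSE]) - nx * (n + 1) / 2
  s <- sqrt(nx * ny * (n + 1) / 12)
  list(r = unname(r), s = rep(s, nrow(dataset$values)))
}

# ranksum r for many permuted labelings at once: ranks do not depend on the
# labels, so permuted r is just a matrix product with the X-membership matrix
ranksum_r_for_labels <- function(ranks, x_member) {
  nx <- colSums(x_member)[1L]
  n <- nrow(x_member)
  ranks %*% x_member - nx * (n + 1) / 2
}

#' Select the fudge factor s0
#'
#' The d-statistic `d = r/(s + s0)` damps per-feature spread estimates with a
#' shared constant `s0` chosen so that the dispersion of `d` is as independent
#' of the spread level as possible. Following the SAM recipe, features are
#' binned by percentiles of `s`; for each candidate `s0` the median absolute
#' deviation of `d` is computed within each bin, and the candidate minimizing
#' the coefficient of variation of those bin-wise MADs wins. Candidates are
#' the type-1 quantiles of `s` at `probs` (actual members of the `{s_i}`
#' pool) plus 0; ties are broken towards the smallest candidate.
#'
#' @param r,s Numeric vectors from [t_components()] or
#'   [ranksum_components()]; `length >= 2`.
#' @param probs Quantile probabilities defining the candidate pool
#'   (default `seq(0, 1, 0.05)`). Pass `NULL` with `candidates` to supply an
#'   explicit pool instead.
#' @param candidates Optional explicit candidate vector (0 is always added).
#' @param n_bins Number of spread bins; default `min(100, max(1, floor(M/2)))`.
#' @return The selected `s0` (nonnegative scalar).
#' @export
select_s0 <- function(r, s, probs = seq(0, 1, by = 0.05),
                      candidates = NULL, n_bins = NULL) {
  M <- length(r)
  if (M < 2L || length(s) != M) stop_input("select_s0 needs r, s of equal length >= 2")
  if (any(s < 0)) stop_input("spreads s must be nonnegative")
  if (is.null(candidates)) {
    candidates <- unname(quantile(s, probs = probs, type = 1))
  }
  candidates <- sort(unique(c(0, candidates)))
  if (all(s == 0) && all(candidates == 0)) {
    if (any(r != 0)) stop_input("degenerate spread: all s_i are zero")
    return(0)
  }
  candidates <- candidates[s0_feasible(s, candidates)]
  crit <- vapply(candidates, function(c0) s0_criterion(r, s, c0, n_bins), numeric(1))
  # smallest candidate among minimizers; all-Inf (flat) also lands on the smallest
  candidates[which.min(crit)]
}

s0_feasible <- function(s, candidates) candidates > 0 | min(s) > 0

# coefficient of variation of bin-wise MADs of d = r/(s + s0); Inf when the
# criterion is undefined (e.g. all bin MADs zero)
s0_criterion <- function(r, s, s0, n_bins = NULL) {
  M <- length(r)
  n_bins <- n_bins %||% min(100L, max(1L, M %/% 2L))
  d <- r / (s + s0)
  bins <- spread_bins(s, n_bins)
  mads <- vapply(split(d, bins), mad, numeric(1))
  mu <- mean(mads)
  if (!is.finite(mu) || mu <= 0) return(Inf)
  cv <- sd(mads) / mu
  if (is.finite(cv)) cv else Inf
}

# equal-count bins by rank of s (deterministic, ties by feature index)
spread_bins <- function(s, n_bins) {
  ord_rank <- rank(s, ties.method = "first")
  as.integer(ceiling(ord_rank * n_bins / length(s)))
}

#' Corrected d-values
#'
#' Elementwise `d_i = r_i / (s_i + s0)`, no clipping.
#'
#' @param r,s Component vectors.
#' @param s0 Nonnegative fudge factor.
#' @return Numeric vector of d-values.
#' @export
d_values <- function(r, s, s0) {
  if (any(s + s0 <= 0)) stop_input("degenerate spread: s_i + s0 must be positive")
  r / (s + s0)
}

#' Compute the full moderated statistic for a dataset
#'
#' Convenience wrapper: components, `s0` selection (unless supplied) and
#' d-values in one step.
#'
#' @inheritParams t_components
#' @param statistic `"t"` (default) or `"ranksum"`.
#' @param s0 Optional fixed fudge factor; selected via [select_s0()] when
#'   `NULL`.
#' @return A list of class `d_statistics`: `r`, `s`, `s0`, `d`,
#'   `statistic`.
#' @export
d_statistics <- function(dataset, statistic = c("t", "ranksum"), s0 = NULL) {
  statistic <- match.arg(statistic)
  comp <- switch(statistic, t = t_components(dataset),
                 ranksum = ranksum_components(dataset))
  if (is.null(s0)) s0 <- select_s0(comp$r, comp$s)
  structure(list(r = comp$r, s = comp$s, s0 = s0,
                 d = d_values(comp$r, comp$s, s0),
                 statistic = statistic),
            class = "d_statistics")
}

#' Per-feature baseline p-values
#'
#' Classical p-values used by the BH and Storey baselines: pooled-variance
#' two-sample t (df = N_X + N_Y - 2) or Wilcoxon rank-sum via the normal
#' approximation with tie correction (no continuity correction). One-sided
#' variants test the upper tail (group X exceeding group Y). Features with
#' zero pooled variance and equal means get p = 1 by convention (no
#' variation, no evidence).
#'
#' @inheritParams t_components
#' @param test One of `"t_two_sided"`, `"t_one_sided"`,
#'   `"ranksum_two_sided"`, `"ranksum_one_sided"`.
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
feature_pvalues <- function(dataset,
                            test = c("t_two_sided", "t_one_sided",
                                     "ranksum_two_sided", "ranksum_one_sided")) {
  test <- match.arg(test)
  idx <- group_indices(dataset)
  nx <- length(idx$x); ny <- length(idx$y)
  if (startsWith(test, "t_")) {
    comp <- t_components(dataset)
    df <- nx + ny - 2
    tt <- ifelse(comp$s > 0, comp$r / comp$s, ifelse(comp$r == 0, 0, Inf * sign(comp$r)))
    p <- if (test == "t_two_sided") 2 * pt(-abs(tt), df) else pt(tt, df, lower.tail = FALSE)
    # zero-variance, zero-difference features carry no evidence
    p[comp$s == 0 & comp$r == 0] <- 1
  } else {
    z <- ranksum_z(dataset$values, idx$x, idx$y)
    p <- if (test == "ranksum_two_sided") 2 * pnorm(-abs(z)) else pnorm(z, lower.tail = FALSE)
    p[is.na(z)] <- 1  # all values tied: null variance zero
  }
  unname(pmin(pmax(p, 0), 1))
}

# tie-corrected rank-sum z-scores, one per feature (vectorized)
ranksum_z <- function(values, ix, iy) {
  nx <- length(ix); ny <- length(iy); n <- nx + ny
  apply(values, 1L, function(v) {
    rk <- rank(v)
    w <- sum(rk[ix])
    tie_tab <- table(v)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sig2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sig2 <= 0) return(NA_real_)
    (w - nx * (n + 1) / 2) / sqrt(sig2)
  })
}
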