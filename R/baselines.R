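#' Benjamini-Hochberg step-up selection
#'
#' Classical step-up: with p-values sorted ascending, reject the hypotheses
#' with the `i` smallest p-values for the largest `i` satisfying
#' `p_(i) <= i * alpha / M` (boundary inclusive). Implemented through
#' [stats::p.adjust()].
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param alpha Target FDR level in (0, 1).
#' @return Integer vector of rejected feature indices (possibly empty).
#' @export
bh_select <- function(p, alpha) {
  check_pvalues(p)
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must lie in (0, 1)")
  which(p.adjust(p, method = "BH") <= alpha)
}

check_pvalues <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop_input("p-values must lie in [0, 1]")
}

#' Storey q-value selection
#'
#' Estimates the null proportion as
#' `pihat0 = min(1, #\{p_i > lambda\} / ((1 - lambda) M))` (floored at `1/M`
#' when zero), forms q-values by the cumulative-minimum construction
#' `q_(i) = min_{j >= i} pihat0 * M * p_(j) / j`, and rejects `q <= alpha`.
#' With `pihat0 = 1` this reduces exactly to BH.
#'
#' @inheritParams bh_select
#' @param lambda Tuning parameter in (0, 1) for the null-proportion
#'   estimate; default 0.5.
#' @return List with `selected` (indices), `q` (per-feature q-values,
#'   original order) and `pi0_hat`.
#' @export
storey_select <- function(p, alpha, lambda = 0.5) {
  check_pvalues(p)
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must lie in (0, 1)")
  if (lambda <= 0 || lambda >= 1) stop_input("lambda must lie in (0, 1)")
  M <- length(p)
  pi0_hat <- min(1, sum(p > lambda) / ((1 - lambda) * M))
  if (pi0_hat == 0) pi0_hat <- 1 / M
  q <- storey_qvalues(p, pi0_hat)
  list(selected = which(q <= alpha), q = q, pi0_hat = pi0_hat)
}

storey_qvalues <- function(p, pi0_hat) {
  M <- length(p)
  ord <- order(p)
  raw <- pi0_hat * M * p[ord] / seq_len(M)
  q_sorted <- rev(cummin(rev(pmin(raw, 1))))
  q <- numeric(M)
  q[ord] <- q_sorted
  q
}

#' SAM delta-threshold rejection region
#'
#' The Delta-value of each (d-sorted) feature is its gap to the expected
#' null order statistic ([delta_values()]). Scanning the positive-d side in
#' ascending d order, the positive cut-off is the d-value of the first
#' feature with `Delta >= delta0`; scanning the negative-d side in
#' descending d order, the negative cut-off is the d-value of the first
#' feature with `Delta <= -delta0`. Cut-offs are applied strictly; a side
#' with no qualifying feature is empty (infinite sentinel).
#'
#' @inheritParams estimate_fdr
#' @param delta0 Positive threshold on the Delta-values.
#' @return List with `tau_pos`, `tau_neg`, `n_pos`, `n_neg` (realized strict
#'   exceedance counts of the observed d-values).
#' @export
sam_delta_select <- function(d, null, delta0) {
  if (delta0 <= 0) stop_input("delta0 must be positive")
  sorted_d <- sort(d)
  sam_select_sorted(sorted_d, sorted_d - null$expected_order_stats, delta0)
}

# delta-threshold selection on presorted inputs; n_pos/n_neg are strict
# exceedance counts of the observed values themselves
sam_select_sorted <- function(sorted_d, delta, delta0) {
  M <- length(sorted_d)
  pos_side <- which(sorted_d > 0)
  hit_pos <- pos_side[delta[pos_side] >= delta0]
  tau_pos <- if (length(hit_pos) > 0) sorted_d[hit_pos[1L]] else Inf

  neg_side <- rev(which(sorted_d < 0))
  hit_neg <- neg_side[delta[neg_side] <= -delta0]
  tau_neg <- if (length(hit_neg) > 0) sorted_d[hit_neg[1L]] else -Inf

  list(tau_pos = tau_pos, tau_neg = tau_neg,
       n_pos = M - findInterval(tau_pos, sorted_d),
       n_neg = findInterval(tau_neg, sorted_d, left.open = TRUE))
}

# FDR of the (n_pos, n_neg) pair from precomputed one-sided counts; NULL when
# the pair is out of the precomputed range
pair_fdr_from_counts <- function(counts, pi0, n_pos, n_neg) {
  if (is.null(counts)) return(NULL)
  if (n_pos > counts$m_rho || n_neg > counts$m_rho) return(NULL)
  tp <- counts$tp_pos[n_pos + 1L] + counts$tp_neg[n_neg + 1L]
  if (tp == 0L) return(NULL)
  med <- median(counts$fp_pos[n_pos + 1L, ] + counts$fp_neg[n_neg + 1L, ])
  min(1, med * as_pi0(pi0) / tp)
}

# default grid per the Delta-search convention: log-spaced over the range of
# positive |Delta| values
default_delta_grid <- function(d, null, length_out = 100L) {
  a <- abs(delta_values(d, null))
  a <- a[a > 0]
  if (length(a) == 0) return(numeric(0))
  exp(seq(log(min(a)), log(max(a)), length.out = length_out))
}

#' Best SAM selection under an FDR cut-off
#'
#' Evaluates the permutation FDR estimate of the region selected by each
#' `delta0` in the grid and returns the qualifying region (estimated FDR
#' strictly below `psi`) with the largest call count (lowest FDR among
#' equal counts). Because every Delta-selected region is one of the
#' positive/negative splits the split-search explores directly, this
#' baseline's call count can never exceed [max_features()]'s at the same
#' cut-off.
#'
#' @inheritParams max_features
#' @param delta_grid Positive thresholds to try; default 100 log-spaced
#'   points spanning the positive `|Delta|` range.
#' @param counts Optional [precompute_counts()] table to speed up the grid
#'   evaluation.
#' @return List with `n_called`, `n_pos`, `n_neg`, `fdr`, `delta0`,
#'   `tau_pos`, `tau_neg`; zero calls (`fdr = NA`) when nothing qualifies.
#' @export
sam_max_features <- function(d, null, pi0, psi, delta_grid = NULL,
                             counts = NULL) {
  if (psi <= 0 || psi >= 1) stop_input("psi must lie strictly between 0 and 1")
  delta_grid <- delta_grid %||% default_delta_grid(d, null)
  sorted_d <- sort(d)
  delta <- sorted_d - null$expected_order_stats
  best <- list(n_called = 0L, n_pos = 0L, n_neg = 0L, fdr = NA_real_,
               delta0 = NA_real_, tau_pos = Inf, tau_neg = -Inf)
  for (delta0 in delta_grid) {
    reg <- sam_select_sorted(sorted_d, delta, delta0)
    n_called <- reg$n_pos + reg$n_neg
    if (n_called == 0L) next
    # score the implied (n_pos, n_neg) pair with the same FDR functional the
    # split search minimizes (an empty side's cut-off is the extreme observed
    # order statistic, not an infinite sentinel), so the bounding argument
    # versus the split search is exact
    fdr <- pair_fdr_from_counts(counts, pi0, reg$n_pos, reg$n_neg) %||%
      tryCatch(estimate_fdr(d, null, pi0, reg$n_pos, reg$n_neg)$fdr,
               mifdr_input_error = function(e) NA_real_)
    if (!is.na(fdr) && fdr < psi &&
        (n_called > best$n_called ||
         (n_called == best$n_called && !is.na(best$fdr) && fdr < best$fdr))) {
      best <- list(n_called = n_called, n_pos = reg$n_pos, n_neg = reg$n_neg,
                   fdr = fdr, delta0 = delta0,
                   tau_pos = reg$tau_pos, tau_neg = reg$tau_neg)
    }
  }
  best
}
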