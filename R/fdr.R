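#' Count values beyond asymmetric cut-offs
#'
#' Strict counts: `n_above = #\{v > tau_pos\}`, `n_below = #\{v < tau_neg\}`.
#' Values exactly equal to a cut-off are not counted — the rejection region
#' `{d > tau_pos or d < tau_neg}` is open at both boundaries.
#'
#' @param values Numeric vector.
#' @param tau_pos,tau_neg Cut-offs (`+Inf`/`-Inf` sentinels allowed);
#'   `tau_neg <= tau_pos`.
#' @return Integer vector `c(n_above, n_below)`.
#' @export
count_exceedances <- function(values, tau_pos, tau_neg) {
  if (tau_neg > tau_pos) stop_input("tau_neg must not exceed tau_pos")
  c(n_above = sum(values > tau_pos), n_below = sum(values < tau_neg))
}

# cut-offs implied by calling the n_pos largest / n_neg smallest observed
# d-values: tau_pos is the (n_pos+1)-th largest (so exactly n_pos lie strictly
# above for distinct d), symmetric below; a fully-open side uses an infinite
# sentinel
region_taus <- function(sorted_d, n_pos, n_neg) {
  M <- length(sorted_d)
  tau_pos <- if (n_pos < M) sorted_d[M - n_pos] else -Inf
  tau_neg <- if (n_neg < M) sorted_d[n_neg + 1L] else Inf
  list(tau_pos = tau_pos, tau_neg = tau_neg)
}

#' Estimate the FDR of an asymmetric rejection region
#'
#' The region calls the `n_pos` features with the largest observed d-values
#' and the `n_neg` with the smallest: cut-offs are taken from the observed
#' order statistics and applied strictly. The false-positive count in each
#' permutation is the number of permuted d-values beyond the cut-offs; the
#' estimate is
#' \deqn{\widehat{FDR} = \min\left(1,\;
#'   \mathrm{median}_b\{FP^+_b + FP^-_b\} \cdot \hat\pi_0 / (TP^+ + TP^-)\right)}
#' with the median over permutations (midpoint of the central pair for even
#' B) and TP the realized strict exceedance counts of the observed d-values
#' themselves (equal to `n_pos`/`n_neg` when observed values are distinct).
#'
#' @param d Observed d-values.
#' @param null A [permutation_null()].
#' @param pi0 A [estimate_pi0()] result or a plain number in (0, 1].
#' @param n_pos,n_neg Numbers of positive / negative calls;
#'   `1 <= n_pos + n_neg <= M`.
#' @return List of class `fdr_estimate`: `fdr`, `fp_median`, `tp_pos`,
#'   `tp_neg`, `n_pos`, `n_neg`, `tau_pos`, `tau_neg`, `pi0`.
#' @export
estimate_fdr <- function(d, null, pi0, n_pos, n_neg) {
  M <- length(d)
  if (n_pos < 0 || n_neg < 0 || n_pos + n_neg < 1 || n_pos + n_neg > M) {
    stop_input("need 1 <= n_pos + n_neg <= M with both counts nonnegative")
  }
  taus <- region_taus(sort(d), n_pos, n_neg)
  fdr_for_region(d, null, pi0, taus$tau_pos, taus$tau_neg,
                 n_pos = n_pos, n_neg = n_neg)
}

# FDR estimate for explicit cut-offs (shared by estimate_fdr and the SAM
# delta selector, which derives its cut-offs differently)
fdr_for_region <- function(d, null, pi0, tau_pos, tau_neg,
                           n_pos = NULL, n_neg = NULL) {
  pi0 <- as_pi0(pi0)
  tp_pos <- sum(d > tau_pos)
  tp_neg <- sum(d < tau_neg)
  if (tp_pos + tp_neg == 0L) {
    stop_input("no observed d-values beyond the cut-offs: FDR undefined")
  }
  fp <- rowSums(null$d_hat > tau_pos) + rowSums(null$d_hat < tau_neg)
  fp_median <- median(fp)
  structure(
    list(fdr = min(1, fp_median * pi0 / (tp_pos + tp_neg)),
         fp_median = fp_median,
         tp_pos = tp_pos, tp_neg = tp_neg,
         n_pos = n_pos %||% tp_pos, n_neg = n_neg %||% tp_neg,
         tau_pos = tau_pos, tau_neg = tau_neg, pi0 = pi0),
    class = "fdr_estimate"
  )
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf("<fdr_estimate> FDR=%.4g at (N+=%d, N-=%d), median FP=%.4g, pi0=%.3f\n",
              x$fdr, x$n_pos, x$n_neg, x$fp_median, x$pi0))
  invisible(x)
}
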