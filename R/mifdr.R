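#' Minimize estimated FDR at a fixed number of calls
#'
#' Calling `N` features splits into `N + 1` options: `n` positive calls (the
#' `n` largest d-values) and `N - n` negative calls (the `N - n` smallest),
#' for `n = 0..N`. Each option's permutation-estimated FDR is evaluated via
#' [estimate_fdr()] and the split with the lowest estimate is returned (ties
#' go to the smallest `n_pos`; splits with zero realized exceedances are
#' skipped). This is a literal scan of all options, so it is optimal at this
#' `N` by construction.
#'
#' @inheritParams estimate_fdr
#' @param n Total number of calls, `1 <= n <= M`.
#' @return A `mifdr_result`: list with `n_total`, `n_pos`, `n_neg`, `fdr`,
#'   `feature_pos`, `feature_neg` (feature indices, largest-d first /
#'   smallest-d first), `found` (logical).
#' @export
minimize_fdr_at_n <- function(d, null, pi0, n) {
  M <- length(d)
  if (n < 1 || n > M) stop_input("n must satisfy 1 <= n <= M")
  best <- NULL
  for (np in 0:n) {
    est <- tryCatch(estimate_fdr(d, null, pi0, np, n - np),
                    mifdr_input_error = function(e) NULL)
    if (!is.null(est) && (is.null(best) || est$fdr < best$fdr)) best <- est
  }
  if (is.null(best)) {
    stop_input("every split of n = %d has zero observed exceedances", n)
  }
  mifdr_result(d, n_total = n, n_pos = best$n_pos, n_neg = best$n_neg,
               fdr = best$fdr, pi0 = as_pi0(pi0))
}

mifdr_result <- function(d, n_total, n_pos, n_neg, fdr, pi0, found = TRUE) {
  ord_desc <- order(-d, seq_along(d))
  ord_asc <- order(d, seq_along(d))
  structure(
    list(n_total = n_total, n_pos = n_pos, n_neg = n_neg, fdr = fdr,
         feature_pos = if (n_pos > 0) ord_desc[seq_len(n_pos)] else integer(0),
         feature_neg = if (n_neg > 0) ord_asc[seq_len(n_neg)] else integer(0),
         pi0 = pi0, found = found),
    class = "mifdr_result"
  )
}

#' @export
print.mifdr_result <- function(x, ...) {
  if (!x$found) {
    cat("<mifdr_result> no qualifying call set found\n")
  } else {
    cat(sprintf("<mifdr_result> N=%d calls (N+=%d, N-=%d), estimated FDR=%.4g\n",
                x$n_total, x$n_pos, x$n_neg, x$fdr))
  }
  invisible(x)
}

#' Precompute one-sided true/false positive counts
#'
#' For `k = 0..m_rho`, the positive-side cut-off is the `(k+1)`-th largest
#' observed d-value and the negative-side cut-off the `(k+1)`-th smallest.
#' `tp_pos[k]` / `tp_neg[k]` count observed d-values strictly beyond those
#' cut-offs (equal to `k` when observed values are distinct), and
#' `fp_pos[k, b]` / `fp_neg[k, b]` count permuted d-values in permutation `b`
#' strictly beyond them. Any `(n_pos, n_neg)` region's false-positive vector
#' is then just `fp_pos[n_pos, ] + fp_neg[n_neg, ]`, which is what makes the
#' max-N search cheap.
#'
#' @inheritParams estimate_fdr
#' @param m_rho Largest one-sided count to precompute (`1 <= m_rho <= M`).
#' @return List of class `precomputed_counts`: integer vectors `tp_pos`,
#'   `tp_neg` (length `m_rho + 1`, index `k+1` holds count for `k`) and
#'   integer matrices `fp_pos`, `fp_neg` (`(m_rho+1) x B`).
#' @export
precompute_counts <- function(d, null, m_rho) {
  M <- length(d)
  if (m_rho < 1 || m_rho > M) stop_input("m_rho must satisfy 1 <= m_rho <= M")
  sorted_d <- sort(d)
  ks <- 0:m_rho
  tau_pos <- ifelse(ks < M, sorted_d[pmax(M - ks, 1L)], -Inf)
  tau_neg <- ifelse(ks < M, sorted_d[pmin(ks + 1L, M)], Inf)
  tp_pos <- M - findInterval(tau_pos, sorted_d)
  tp_neg <- findInterval(tau_neg, sorted_d, left.open = TRUE)
  B <- null$B
  fp_pos <- matrix(0L, m_rho + 1L, B)
  fp_neg <- matrix(0L, m_rho + 1L, B)
  for (b in seq_len(B)) {
    row <- null$sorted_d_hat[b, ]
    fp_pos[, b] <- length(row) - findInterval(tau_pos, row)
    fp_neg[, b] <- findInterval(tau_neg, row, left.open = TRUE)
  }
  structure(list(tp_pos = as.integer(tp_pos), tp_neg = as.integer(tp_neg),
                 fp_pos = fp_pos, fp_neg = fp_neg,
                 tau_pos = tau_pos, tau_neg = tau_neg, m_rho = m_rho),
            class = "precomputed_counts")
}

#' Maximum number of calls under an FDR cut-off
#'
#' Scans the total call count `k` downward from `m_rho`; at each `k` the
#' estimated FDR is minimized over all `k + 1` positive/negative splits using
#' the precomputed one-sided counts, and the first `k` whose minimized
#' estimate falls strictly below `psi` is returned together with its
#' minimizing split. Because the minimized FDR at each `k` is the best
#' achievable over every split, the returned `k` is the maximum call count
#' any split-based selection can reach under `psi` (this is the method's
#' optimality guarantee, tested against brute force).
#'
#' @inheritParams estimate_fdr
#' @param psi FDR cut-off in (0, 1); the comparison is strict (`< psi`).
#' @param m_rho Cap on the call counts examined (default 1000, clipped to
#'   M).
#' @param counts Optional [precompute_counts()] result to reuse.
#' @return A `mifdr_result`; `found = FALSE` (zero calls) when no `k >= 1`
#'   qualifies.
#' @export
max_features <- function(d, null, pi0, psi, m_rho = 1000L, counts = NULL) {
  if (psi <= 0 || psi >= 1) stop_input("psi must lie strictly between 0 and 1")
  m_rho <- min(m_rho, length(d))
  if (is.null(counts)) counts <- precompute_counts(d, null, m_rho)
  hit <- scan_descend_cpp(counts$fp_pos, counts$fp_neg,
                          counts$tp_pos, counts$tp_neg,
                          as_pi0(pi0), psi, m_rho)
  if (hit$k < 1L) {
    return(mifdr_result(d, n_total = 0L, n_pos = 0L, n_neg = 0L,
                        fdr = NA_real_, pi0 = as_pi0(pi0), found = FALSE))
  }
  mifdr_result(d, n_total = hit$k, n_pos = hit$n_pos,
               n_neg = hit$k - hit$n_pos, fdr = hit$fdr, pi0 = as_pi0(pi0))
}

# minimized-FDR curve: for every total call count k = 0..kmax, the best
# split's estimated FDR and its n_pos (fast path used by the study)
min_fdr_curve <- function(counts, pi0, kmax) {
  res <- scan_splits_cpp(counts$fp_pos, counts$fp_neg,
                         counts$tp_pos, counts$tp_neg,
                         as_pi0(pi0), as.integer(kmax))
  tibble(n_called = 0:kmax,
         est_fdr = res$min_fdr,
         n_pos = res$best_n_pos)
}

#' Fit the FDR-minimizing caller to a dataset
#'
#' End-to-end convenience wrapper: computes the moderated d-statistic
#' (including `s0` selection), generates the permutation null, estimates
#' `pi0`, and either finds the maximum call count under `psi`
#' (`mode = "max_features"`) or the best split at a fixed total `n`
#' (`mode = "fixed_n"`). Supports [tidy()] (per-feature table),
#' [glance()] (one-row summary) and [autoplot()] (observed vs expected
#' order-statistic plot).
#'
#' @inheritParams permutation_null
#' @param mode `"max_features"` or `"fixed_n"`.
#' @param psi FDR cut-off for `max_features` mode.
#' @param n Total calls for `fixed_n` mode.
#' @param m_rho Search cap for `max_features` mode.
#' @param pi0_window Null quantile window for [estimate_pi0()].
#' @return An object of class `mifdr_fit`.
#' @export
mifdr <- function(dataset, statistic = c("t", "ranksum"),
                  mode = c("max_features", "fixed_n"),
                  psi = 0.05, n = NULL, B = 100L, seed = 1L,
                  m_rho = 1000L, pi0_window = c(0.25, 0.75)) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  stats <- d_statistics(dataset, statistic)
  null <- permutation_null(dataset, statistic, B = B, seed = seed, s0 = stats$s0)
  pi0 <- estimate_pi0(stats$d, null, window = pi0_window)
  result <- if (mode == "max_features") {
    max_features(stats$d, null, pi0, psi, m_rho)
  } else {
    if (is.null(n)) stop_input("mode 'fixed_n' requires n")
    minimize_fdr_at_n(stats$d, null, pi0, n)
  }
  structure(
    list(result = result, stats = stats, null = null, pi0 = pi0,
         feature_ids = rownames(dataset$values),
         mode = mode, psi = if (mode == "max_features") psi else NA_real_,
         B = null$B, seed = seed),
    class = "mifdr_fit"
  )
}

#' @export
print.mifdr_fit <- function(x, ...) {
  cat(sprintf("<mifdr_fit> %s statistic, s0=%.4g, B=%d, pi0=%.3f\n",
              x$stats$statistic, x$stats$s0, x$B, x$pi0$pi0))
  print(x$result)
  invisible(x)
}

#' @describeIn mifdr Per-feature tibble: `feature_id`, `d_value`, `sign`,
#'   `called`.
#' @param x A `mifdr_fit`.
#' @param ... Unused.
#' @export
tidy.mifdr_fit <- function(x, ...) {
  d <- x$stats$d
  called <- logical(length(d))
  called[c(x$result$feature_pos, x$result$feature_neg)] <- TRUE
  sign_chr <- ifelse(seq_along(d) %in% x$result$feature_neg, "-",
                     ifelse(seq_along(d) %in% x$result$feature_pos, "+",
                            ifelse(d >= 0, "+", "-")))
  tibble(feature_id = x$feature_ids %||% paste0("f", seq_along(d)),
         d_value = d, sign = sign_chr, called = called)
}

#' @describeIn mifdr One-row summary tibble: calls, split, FDR, pi0, s0, B.
#' @export
glance.mifdr_fit <- function(x, ...) {
  tibble(n_called = x$result$n_total, n_pos = x$result$n_pos,
         n_neg = x$result$n_neg, fdr = x$result$fdr,
         pi0 = x$pi0$pi0, s0 = x$stats$s0, B = x$B,
         statistic = x$stats$statistic, psi = x$psi)
}

#' Quantile plot of a fit
#'
#' Observed sorted d-values against the expected null order statistics, with
#' called features highlighted — the standard diagnostic for permutation
#' based significance callers.
#'
#' @param object A `mifdr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mifdr_fit <- function(object, ...) {
  d <- object$stats$d
  ord <- order(d, seq_along(d))
  df <- tibble(expected = object$null$expected_order_stats,
               observed = d[ord],
               called = ord %in% c(object$result$feature_pos,
                                   object$result$feature_neg))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed,
                                   colour = .data$called)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(x = "expected null order statistic",
                  y = "observed d-value", colour = "called")
}

#' Export a fit as a result table
#'
#' @param fit A `mifdr_fit`.
#' @return A [result_table()] ready for [write_results()].
#' @export
as_result_table <- function(fit) {
  stopifnot(inherits(fit, "mifdr_fit"))
  result_table(tidy(fit),
               meta = list(n_pos = fit$result$n_pos, n_neg = fit$result$n_neg,
                           fdr = if (is.na(fit$result$fdr)) 0 else fit$result$fdr,
                           pi0 = fit$pi0$pi0, B = fit$B, seed = fit$seed))
}
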