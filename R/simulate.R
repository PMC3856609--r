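#' Define a simulation scenario
#'
#' A scenario is a table of feature categories, each drawing the two groups'
#' measurements independently from stated distributions, plus the per-group
#' sample size. Categories whose two distributions differ are ground-truth
#' alternatives. [benchmark_scenario()] builds the default benchmark mixture:
#' 10000 null features (5000 standard normal in both groups, 5000 uniform on
#' \[-3, 3\] in both groups) and 400 alternatives (50 N(0,1) vs N(-2,1);
#' 150 N(0,1) vs N(1,1); 150 U\[-3,3\] vs U\[-2,4\]; 50 U\[-3,3\] vs
#' U\[-1.5,4.5\]), 8 samples per group.
#'
#' @param categories Data frame with columns `n_features`, `dist1`, `a1`,
#'   `b1`, `dist2`, `a2`, `b2`, `alternative`. `dist*` is `"normal"`
#'   (mean, sd) or `"uniform"` (min, max).
#' @param n_per_group Samples per group (>= 2).
#' @return A `sim_scenario` object.
#' @export
simulation_scenario <- function(categories, n_per_group = 8L) {
  categories <- as_tibble(categories)
  needed <- c("n_features", "dist1", "a1", "b1", "dist2", "a2", "b2", "alternative")
  if (!all(needed %in% names(categories))) {
    stop_input("categories needs columns: %s", paste(needed, collapse = ", "))
  }
  if (any(categories$n_features <= 0)) stop_input("category feature counts must be positive")
  if (!all(c(categories$dist1, categories$dist2) %in% c("normal", "uniform"))) {
    stop_input("distributions must be 'normal' or 'uniform'")
  }
  if (n_per_group < 2L) stop_input("n_per_group must be >= 2")
  structure(list(categories = categories, n_per_group = as.integer(n_per_group)),
            class = "sim_scenario")
}

#' @rdname simulation_scenario
#' @param null_only Drop the alternative categories (pure-null data).
#' @export
benchmark_scenario <- function(n_per_group = 8L, null_only = FALSE) {
  cat_tbl <- tibble(
    n_features = c(5000L, 5000L, 50L, 150L, 150L, 50L),
    dist1 = c("normal", "uniform", "normal", "normal", "uniform", "uniform"),
    a1 = c(0, -3, 0, 0, -3, -3),
    b1 = c(1, 3, 1, 1, 3, 3),
    dist2 = c("normal", "uniform", "normal", "normal", "uniform", "uniform"),
    a2 = c(0, -3, -2, 1, -2, -1.5),
    b2 = c(1, 3, 1, 1, 4, 4.5),
    alternative = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
  if (null_only) cat_tbl <- cat_tbl[!cat_tbl$alternative, ]
  simulation_scenario(cat_tbl, n_per_group)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> %d features (%d alternative), %d samples per group\n",
              sum(x$categories$n_features),
              sum(x$categories$n_features[x$categories$alternative]),
              x$n_per_group))
  invisible(x)
}

#' Draw one synthetic dataset from a scenario
#'
#' Every feature's group-1 and group-2 measurements are drawn independently
#' from its category's distributions; bit-reproducible from `seed`.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Integer seed.
#' @return List with `dataset` (an [expression_dataset()], groups `"g1"` /
#'   `"g2"`, X = g1) and `truth` (logical vector, `TRUE` = alternative).
#' @export
simulate_dataset <- function(scenario, seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  npg <- scenario$n_per_group
  cats <- scenario$categories
  with_seed(seed, {
    blocks <- lapply(seq_len(nrow(cats)), function(i) {
      m <- cats$n_features[i]
      g1 <- draw_block(cats$dist1[i], cats$a1[i], cats$b1[i], m, npg)
      g2 <- draw_block(cats$dist2[i], cats$a2[i], cats$b2[i], m, npg)
      cbind(g1, g2)
    })
    values <- do.call(rbind, blocks)
    truth <- rep(cats$alternative, times = cats$n_features)
    dataset <- expression_dataset(
      values, labels = rep(c("g1", "g2"), each = npg),
      feature_ids = paste0("f", seq_len(nrow(values))),
      sample_ids = paste0("s", seq_len(2L * npg))
    )
    list(dataset = dataset, truth = truth)
  })
}

draw_block <- function(dist, a, b, m, n) {
  k <- m * n
  vals <- switch(dist,
                 normal = rnorm(k, mean = a, sd = b),
                 uniform = runif(k, min = a, max = b))
  matrix(vals, nrow = m, ncol = n)
}

#' Realized (true) FDR of a call set
#'
#' With ground truth known, the fraction of truth-null features among those
#' called.
#'
#' @param called Integer indices of called features (nonempty).
#' @param truth Logical vector, `TRUE` = alternative.
#' @return A number in \[0, 1\].
#' @export
true_fdr <- function(called, truth) {
  if (length(called) == 0L) stop_input("true_fdr needs a nonempty call set")
  sum(!truth[called]) / length(called)
}

#' Run the replicated method-comparison study
#'
#' For each replicate a dataset is drawn from the scenario and every method
#' is run on it: calls at the estimated-FDR cut-off `psi` are recorded, plus
#' the full estimated-FDR and true-FDR versus number-of-calls curves, which
#' are then averaged across replicates aligned on the call count. Per-
#' replicate seeds are `base_seed + replicate`, so individual replicates are
#' reproducible in isolation.
#'
#' Methods: `"mifdr"` (split-minimizing search), `"sam"` (Delta-threshold
#' grid), `"bh"` / `"storey"` (two-sided t p-values by default),
#' `"bh_ranksum"` / `"storey_ranksum"` (rank-sum p-value variants).
#'
#' @param scenario A [simulation_scenario()].
#' @param methods Character vector of method names.
#' @param replicates Number of replicates (>= 1).
#' @param psi Estimated-FDR cut-off for the calls-at-cut-off comparison.
#' @param B Permutations per replicate.
#' @param base_seed Base integer seed.
#' @param n_curve Largest call count tracked in the averaged curves.
#' @param m_rho Search cap passed to [max_features()].
#' @param statistic d-statistic form for the permutation methods.
#' @param storey_lambda Storey's lambda.
#' @return An object of class `fdr_study` with elements `calls`
#'   (per-replicate tibble: replicate, method, n_called, true_fdr, pi0),
#'   `curves` (averaged tibble: method, n_called, mean_est_fdr,
#'   mean_true_fdr, n_reps), `summary` (per-method means), `paired`
#'   (per-replicate miFDR minus SAM call difference, when both methods ran),
#'   `psi`, `replicates`.
#' @export
run_study <- function(scenario, methods = c("mifdr", "sam", "bh", "storey"),
                      replicates = 10L, psi = 0.05, B = 100L,
                      base_seed = 1L, n_curve = 100L, m_rho = 1000L,
                      statistic = "t", storey_lambda = 0.5) {
  known <- c("mifdr", "sam", "bh", "storey", "bh_ranksum", "storey_ranksum")
  bad <- setdiff(methods, known)
  if (length(bad) > 0L) stop_input("unknown method name: %s", bad[1L])
  if (replicates < 1L) stop_input("replicates must be >= 1")

  calls <- list(); curve_acc <- list()
  for (r in seq_len(replicates)) {
    rep_out <- run_one_replicate(scenario, methods, psi, B,
                                 seed = base_seed + r, n_curve = n_curve,
                                 m_rho = m_rho, statistic = statistic,
                                 storey_lambda = storey_lambda)
    calls[[r]] <- dplyr::mutate(rep_out$calls, replicate = r, .before = 1L)
    curve_acc[[r]] <- rep_out$curves
  }
  calls <- dplyr::bind_rows(calls)
  curves <- dplyr::bind_rows(curve_acc) |>
    dplyr::group_by(.data$method, .data$n_called) |>
    dplyr::summarise(
      mean_est_fdr = mean(.data$est_fdr, na.rm = TRUE),
      mean_true_fdr = mean(.data$true_fdr, na.rm = TRUE),
      n_reps = sum(!is.na(.data$est_fdr)),
      .groups = "drop"
    )
  summary_tbl <- calls |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_calls = mean(.data$n_called),
      sd_calls = sd(.data$n_called),
      mean_true_fdr = mean(.data$true_fdr, na.rm = TRUE),
      mean_pi0 = mean(.data$pi0, na.rm = TRUE),
      .groups = "drop"
    )
  paired <- if (all(c("mifdr", "sam") %in% methods)) {
    wide <- tidyr::pivot_wider(calls[, c("replicate", "method", "n_called")],
                               names_from = "method", values_from = "n_called")
    wide$mifdr - wide$sam
  } else {
    NULL
  }
  structure(list(calls = calls, curves = curves, summary = summary_tbl,
                 paired = paired, psi = psi, replicates = replicates,
                 scenario = scenario, B = B, base_seed = base_seed),
            class = "fdr_study")
}

run_one_replicate <- function(scenario, methods, psi, B, seed, n_curve,
                              m_rho, statistic, storey_lambda) {
  sim <- simulate_dataset(scenario, seed)
  ds <- sim$dataset; truth <- sim$truth
  M <- nrow(ds$values)
  n_curve <- min(n_curve, M)
  need_perm <- any(methods %in% c("mifdr", "sam"))

  d <- NULL; null <- NULL; pi0 <- NULL; counts <- NULL
  cum_null_top <- cum_null_bot <- NULL
  if (need_perm) {
    stats <- d_statistics(ds, statistic)
    null <- permutation_null(ds, statistic, B = B, seed = seed + 500000L,
                             s0 = stats$s0)
    d <- stats$d
    pi0 <- estimate_pi0(d, null)
    counts <- precompute_counts(d, null, min(m_rho, M))
    ord_desc <- order(-d, seq_along(d))
    ord_asc <- order(d, seq_along(d))
    cum_null_top <- c(0, cumsum(!truth[ord_desc]))
    cum_null_bot <- c(0, cumsum(!truth[ord_asc]))
  }

  calls <- list(); curves <- list()
  for (m in methods) {
    out <- switch(
      m,
      mifdr = replicate_mifdr(d, null, pi0, counts, psi, n_curve,
                              cum_null_top, cum_null_bot),
      sam = replicate_sam(d, null, pi0, counts, psi, n_curve,
                          cum_null_top, cum_null_bot),
      bh = replicate_pvalue("bh", ds, truth, psi, n_curve, "t_two_sided",
                            storey_lambda),
      storey = replicate_pvalue("storey", ds, truth, psi, n_curve,
                                "t_two_sided", storey_lambda),
      bh_ranksum = replicate_pvalue("bh", ds, truth, psi, n_curve,
                                    "ranksum_two_sided", storey_lambda),
      storey_ranksum = replicate_pvalue("storey", ds, truth, psi, n_curve,
                                        "ranksum_two_sided", storey_lambda)
    )
    out$calls$method <- m
    out$curves$method <- m
    out$calls$pi0 <- if (need_perm) pi0$pi0 else NA_real_
    calls[[m]] <- out$calls
    curves[[m]] <- out$curves
  }
  list(calls = dplyr::bind_rows(calls), curves = dplyr::bind_rows(curves))
}

# true FDR of the best split at each total call count, from cumulative null
# counts in sorted-d order
split_true_fdr <- function(n_pos, n_total, cum_null_top, cum_null_bot) {
  ifelse(n_total > 0 & !is.na(n_pos),
         (cum_null_top[n_pos + 1L] + cum_null_bot[n_total - n_pos + 1L]) /
           n_total,
         NA_real_)
}

replicate_mifdr <- function(d, null, pi0, counts, psi, n_curve,
                            cum_null_top, cum_null_bot) {
  hit <- max_features(d, null, pi0, psi, m_rho = counts$m_rho, counts = counts)
  tf_at_psi <- if (hit$found) {
    true_fdr_of_split(hit$n_pos, hit$n_neg, cum_null_top, cum_null_bot)
  } else {
    NA_real_
  }
  curve <- min_fdr_curve(counts, pi0, n_curve)
  curve <- curve[curve$n_called >= 1L, ]
  curve$est_fdr[!is.finite(curve$est_fdr)] <- NA_real_
  curve$true_fdr <- split_true_fdr(curve$n_pos, curve$n_called,
                                   cum_null_top, cum_null_bot)
  list(calls = tibble(n_called = hit$n_total, true_fdr = tf_at_psi),
       curves = curve[, c("n_called", "est_fdr", "true_fdr")])
}

true_fdr_of_split <- function(n_pos, n_neg, cum_null_top, cum_null_bot) {
  (cum_null_top[n_pos + 1L] + cum_null_bot[n_neg + 1L]) / (n_pos + n_neg)
}

replicate_sam <- function(d, null, pi0, counts, psi, n_curve,
                          cum_null_top, cum_null_bot) {
  grid <- default_delta_grid(d, null)
  sorted_d <- sort(d)
  delta <- sorted_d - null$expected_order_stats
  n_called <- integer(length(grid)); est <- rep(NA_real_, length(grid))
  tf <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    reg <- sam_select_sorted(sorted_d, delta, grid[i])
    nc <- reg$n_pos + reg$n_neg
    n_called[i] <- nc
    if (nc == 0L) next
    f <- pair_fdr_from_counts(counts, pi0, reg$n_pos, reg$n_neg)
    if (is.null(f)) next
    est[i] <- f
    tf[i] <- true_fdr_of_split(reg$n_pos, reg$n_neg, cum_null_top, cum_null_bot)
  }
  qual <- which(!is.na(est) & est < psi)
  if (length(qual) > 0L) {
    best <- qual[order(-n_called[qual], est[qual])][1L]
    calls <- tibble(n_called = n_called[best], true_fdr = tf[best])
  } else {
    calls <- tibble(n_called = 0L, true_fdr = NA_real_)
  }
  curve <- tibble(n_called = seq_len(n_curve), est_fdr = NA_real_,
                  true_fdr = NA_real_)
  for (N in seq_len(n_curve)) {
    at_n <- which(n_called == N & !is.na(est))
    if (length(at_n) > 0L) {
      b <- at_n[which.min(est[at_n])]
      curve$est_fdr[N] <- est[b]
      curve$true_fdr[N] <- tf[b]
    }
  }
  list(calls = calls, curves = curve)
}

replicate_pvalue <- function(kind, ds, truth, psi, n_curve, test, storey_lambda) {
  p <- feature_pvalues(ds, test)
  M <- length(p)
  if (kind == "bh") {
    sel <- bh_select(p, psi)
    q <- pmin(p.adjust(p, method = "BH"), 1)
  } else {
    st <- storey_select(p, psi, lambda = storey_lambda)
    sel <- st$selected
    q <- st$q
  }
  calls <- tibble(
    n_called = length(sel),
    true_fdr = if (length(sel) > 0L) true_fdr(sel, truth) else NA_real_
  )
  ord <- order(p, seq_len(M))
  q_sorted <- q[ord]
  null_cum <- cumsum(!truth[ord])
  idx <- seq_len(min(n_curve, M))
  curve <- tibble(n_called = idx,
                  est_fdr = q_sorted[idx],
                  true_fdr = null_cum[idx] / idx)
  list(calls = calls, curves = curve)
}

#' @export
print.fdr_study <- function(x, ...) {
  cat(sprintf("<fdr_study> %d replicates, psi=%.3g, B=%d\n",
              x$replicates, x$psi, x$B))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @describeIn run_study Averaged curves tibble (`method`, `n_called`,
#'   `mean_est_fdr`, `mean_true_fdr`, `n_reps`).
#' @param x,object An `fdr_study`.
#' @param ... Unused.
#' @export
tidy.fdr_study <- function(x, ...) x$curves

#' @describeIn run_study Per-method summary tibble (mean and sd of calls at
#'   the cut-off, mean realized FDR, mean pi0).
#' @export
glance.fdr_study <- function(x, ...) x$summary

#' @describeIn run_study Averaged estimated- and true-FDR curves per method.
#' @export
autoplot.fdr_study <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves,
                              cols = c("mean_est_fdr", "mean_true_fdr"),
                              names_to = "kind", values_to = "fdr")
  long$kind <- ifelse(long$kind == "mean_est_fdr", "estimated", "true")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_called, y = .data$fdr,
                                     colour = .data$method,
                                     linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of significant features", y = "mean FDR",
                  colour = "method", linetype = "FDR")
}
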