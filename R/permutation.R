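#' Generate the permutation null of the d-statistic
#'
#' Random relabelings of the samples (preserving the two group sizes) are
#' drawn and the d-statistic is recomputed under each, reusing the `s0`
#' selected once on the original labelling so observed and null d-values
#' share a scale. When the number of distinct labelings (`choose(W, N_X)`)
#' is at most `B`, all of them are enumerated exactly; when it is at most
#' `10 * B`, distinct labelings are sampled without replacement; otherwise
#' labelings are drawn uniformly with replacement.
#'
#' @inheritParams t_components
#' @param statistic `"t"` or `"ranksum"`.
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed; the null is bit-reproducible from it.
#' @param s0 Optional fudge factor; defaults to the value selected on the
#'   observed labelling.
#' @param mode `"auto"` (size-based policy above), `"exhaustive"` (all
#'   distinct labelings are used; it is an error to request more permutations
#'   than exist), or `"sample"`.
#' @return An object of class `permutation_null`: list with `d_hat`
#'   (B x M matrix of permuted d-values), `sorted_d_hat` (each row sorted
#'   ascending), `expected_order_stats` (column means of `sorted_d_hat`),
#'   `B`, `seed`, `s0`, `statistic`.
#' @export
permutation_null <- function(dataset, statistic = c("t", "ranksum"),
                             B = 100L, seed = 1L, s0 = NULL,
                             mode = c("auto", "exhaustive", "sample")) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  if (B < 1L) stop_input("B must be >= 1")
  idx <- group_indices(dataset)
  nx <- length(idx$x); W <- ncol(dataset$values)
  n_distinct <- choose(W, nx)

  if (is.null(s0)) {
    comp <- switch(statistic, t = t_components(dataset),
                   ranksum = ranksum_components(dataset))
    s0 <- select_s0(comp$r, comp$s)
  }

  exhaustive <- mode == "exhaustive" || (mode == "auto" && n_distinct <= B)
  if (mode == "exhaustive" && B > n_distinct) {
    stop_input("exhaustive mode: B (%d) exceeds the %d distinct labelings",
               B, n_distinct)
  }

  x_sets <- with_seed(seed, {
    if (exhaustive) {
      utils::combn(W, nx, simplify = FALSE)
    } else if (mode == "auto" && n_distinct <= 10 * B) {
      sample_labelings_distinct(W, nx, B)
    } else {
      replicate(B, sort(sample.int(W, nx)), simplify = FALSE)
    }
  })
  B_eff <- length(x_sets)

  d_hat <- permuted_d(dataset$values, x_sets, statistic, s0)
  sorted <- t(apply(d_hat, 1L, sort))
  structure(
    list(d_hat = d_hat,
         sorted_d_hat = sorted,
         expected_order_stats = colMeans(sorted),
         B = B_eff, seed = seed, s0 = s0, statistic = statistic),
    class = "permutation_null"
  )
}

# run code with a locally-set RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# distinct labelings without replacement: rejection-sample codes until B unique
sample_labelings_distinct <- function(W, nx, B) {
  n_distinct <- choose(W, nx)
  B <- min(B, n_distinct)
  seen <- character(0)
  out <- vector("list", B)
  got <- 0L
  while (got < B) {
    cand <- sort(sample.int(W, nx))
    key <- paste(cand, collapse = ",")
    if (!key %in% seen) {
      got <- got + 1L
      seen <- c(seen, key)
      out[[got]] <- cand
    }
  }
  out
}

# B x M matrix of d-values under the given group-X index sets; all-permutation
# group means/variances via matrix products against the membership matrix
permuted_d <- function(values, x_sets, statistic, s0) {
  M <- nrow(values); W <- ncol(values); Bn <- length(x_sets)
  nx <- length(x_sets[[1L]]); ny <- W - nx
  Xm <- matrix(0, W, Bn)
  for (b in seq_len(Bn)) Xm[x_sets[[b]], b] <- 1
  if (statistic == "t") {
    Ym <- 1 - Xm
    mx <- (values %*% Xm) / nx
    my <- (values %*% Ym) / ny
    v2 <- values * values
    ssx <- (v2 %*% Xm) - nx * mx * mx
    ssy <- (v2 %*% Ym) - ny * my * my
    s <- sqrt(pmax(ssx + ssy, 0) * (1 / nx + 1 / ny) / (nx + ny - 2))
    d <- (mx - my) / (s + s0)
  } else {
    ranks <- t(apply(values, 1L, rank))
    if (M == 1L) ranks <- matrix(ranks, nrow = 1L)
    s <- sqrt(nx * ny * (W + 1) / 12)
    d <- ranksum_r_for_labels(ranks, Xm) / (s + s0)
  }
  t(d)  # B x M
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> B=%d permutations x %d features (%s statistic, s0=%.4g)\n",
              x$B, ncol(x$d_hat), x$statistic, x$s0))
  invisible(x)
}

#' Estimate the null proportion pi0
#'
#' Storey-type quantile recipe shared by SAM: pi0 is the fraction of observed
#' d-values falling inside the central window of the pooled permuted
#' d-values, divided by the window mass. With the default 25–75% window,
#' `pi0 = min(1, #\{q25 <= d_i <= q75\} / (0.5 M))`. A zero estimate is
#' floored at `1/M` so downstream FDR estimates are never degenerately zero.
#' Quantiles use linear interpolation (type 7).
#'
#' @param d Observed d-values (length M >= 4).
#' @param null A [permutation_null()].
#' @param window Two probabilities defining the null quantile window.
#' @return List of class `pi0_estimate` with `pi0` and `window`.
#' @export
estimate_pi0 <- function(d, null, window = c(0.25, 0.75)) {
  M <- length(d)
  if (M < 4L) stop_input("estimate_pi0 needs at least 4 features")
  if (length(window) != 2L || window[1] >= window[2]) {
    stop_input("window must be two increasing probabilities")
  }
  qs <- quantile(null$d_hat, probs = window, type = 7, names = FALSE)
  inside <- sum(d >= qs[1] & d <= qs[2])
  pi0 <- min(1, inside / ((window[2] - window[1]) * M))
  if (pi0 == 0) pi0 <- 1 / M
  structure(list(pi0 = pi0, window = window), class = "pi0_estimate")
}

as_pi0 <- function(pi0) {
  if (inherits(pi0, "pi0_estimate")) pi0$pi0 else as.numeric(pi0)
}

#' Delta-values (observed vs expected null order statistics)
#'
#' Features are sorted ascending by observed d; `Delta_i` is the gap between
#' the i-th smallest observed d and the mean i-th order statistic of the
#' permuted d-values. The SAM selector thresholds these gaps; they need not
#' be monotone in d, which is exactly the failure mode the split-search
#' method avoids.
#'
#' @inheritParams estimate_pi0
#' @return Numeric vector of length M, aligned to ascending-sorted `d`.
#' @export
delta_values <- function(d, null) {
  sort(d) - null$expected_order_stats
}
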