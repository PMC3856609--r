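# Fixture builders and independent oracles. Oracles are written as plain
# loops, independent of the package's vectorized/compiled paths.

# small two-group dataset with gaussian noise
make_dataset <- function(M = 6, nx = 3, ny = 3, seed = 1, shift = 0) {
  set.seed(seed)
  values <- matrix(rnorm(M * (nx + ny)), nrow = M)
  values[1, seq_len(nx)] <- values[1, seq_len(nx)] + shift
  expression_dataset(values, labels = rep(c("A", "B"), c(nx, ny)))
}

# permutation_null object from an explicit permuted d matrix (rows = perms)
manual_null <- function(d_hat, s0 = 0, statistic = "t") {
  d_hat <- as.matrix(d_hat)
  sorted <- t(apply(d_hat, 1, sort))
  if (nrow(d_hat) == 1L) sorted <- matrix(sorted, nrow = 1L)
  structure(list(d_hat = d_hat, sorted_d_hat = sorted,
                 expected_order_stats = colMeans(sorted),
                 B = nrow(d_hat), seed = NA_integer_, s0 = s0,
                 statistic = statistic),
            class = "permutation_null")
}

# random observed-plus-null instance: mixed signs, optional ties
rand_instance <- function(M = 20, B = 4, seed = 1, ties = FALSE) {
  set.seed(seed)
  d <- rnorm(M) * sample(c(0.5, 1, 2), M, replace = TRUE)
  d_hat <- matrix(rnorm(B * M), nrow = B)
  if (ties) {
    d[sample(M, 2)] <- d[sample(M, 1)]
    d_hat[1, 1:2] <- d[1]
  }
  list(d = d, null = manual_null(d_hat), pi0 = runif(1, 0.5, 1))
}

# loop-based FDR estimate for a (n_pos, n_neg) pair; NA when undefined
oracle_pair_fdr <- function(d, d_hat, pi0, n_pos, n_neg) {
  M <- length(d)
  sd_ <- sort(d)
  tau_pos <- if (n_pos < M) sd_[M - n_pos] else -Inf
  tau_neg <- if (n_neg < M) sd_[n_neg + 1] else Inf
  tp <- sum(d > tau_pos) + sum(d < tau_neg)
  if (tp == 0) return(NA_real_)
  fp <- numeric(nrow(d_hat))
  for (b in seq_len(nrow(d_hat))) {
    fp[b] <- sum(d_hat[b, ] > tau_pos) + sum(d_hat[b, ] < tau_neg)
  }
  min(1, median(fp) * pi0 / tp)
}

# exhaustive max-N search over every (n_pos, n_neg) pair
oracle_max_features <- function(d, d_hat, pi0, psi, m_rho = length(d)) {
  M <- length(d)
  best_k <- 0L; best_n <- NA_integer_; best_fdr <- NA_real_
  for (k in 1:min(m_rho, M)) {
    kmin <- Inf; kn <- NA_integer_
    for (n in 0:k) {
      f <- oracle_pair_fdr(d, d_hat, pi0, n, k - n)
      if (!is.na(f) && f < kmin) { kmin <- f; kn <- n }
    }
    if (is.finite(kmin) && kmin < psi && k > best_k) {
      best_k <- k; best_n <- kn; best_fdr <- kmin
    }
  }
  list(n_total = best_k, n_pos = best_n, fdr = best_fdr)
}

# loop-based s0 criterion identical in definition to the package's
oracle_s0 <- function(r, s, candidates, n_bins = NULL) {
  M <- length(r)
  if (is.null(n_bins)) n_bins <- min(100, max(1, M %/% 2))
  rk <- rank(s, ties.method = "first")
  bins <- ceiling(rk * n_bins / M)
  crits <- sapply(candidates, function(c0) {
    d <- r / (s + c0)
    mads <- sapply(sort(unique(bins)), function(bb) mad(d[bins == bb]))
    mu <- mean(mads)
    cv <- if (!is.finite(mu) || mu <= 0) Inf else sd(mads) / mu
    if (is.finite(cv)) cv else Inf
  })
  candidates[which.min(crits)]
}

# write a toy expression fixture to tempdir; returns the two paths
write_fixture_files <- function(dataset, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mp <- file.path(dir, "matrix.tsv")
  lp <- file.path(dir, "labels.tsv")
  write_expression(dataset, mp, lp)
  list(matrix = mp, labels = lp, dir = dir)
}
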