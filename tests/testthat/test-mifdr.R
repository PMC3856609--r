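test_that("fixed-N minimization equals the brute-force split scan", {
  for (seed in 1:8) {
    inst <- rand_instance(M = 14, B = 5, seed = seed, ties = seed %% 3 == 0)
    for (N in c(1, 3, 6)) {
      got <- minimize_fdr_at_n(inst$d, inst$null, inst$pi0, N)
      # argmin property against every split
      fdrs <- sapply(0:N, function(np) {
        oracle_pair_fdr(inst$d, inst$null$d_hat, inst$pi0, np, N - np)
      })
      expect_equal(got$fdr, min(fdrs, na.rm = TRUE))
      expect_equal(got$n_pos, which.min(fdrs) - 1L)  # smallest minimizer
      expect_equal(got$n_pos + got$n_neg, N)
      expect_length(got$feature_pos, got$n_pos)
      expect_length(got$feature_neg, got$n_neg)
    }
  }
})

test_that("with all-positive d the minimizer puts every call on the positive side", {
  d <- c(0.5, 1, 2, 3, 4, 5)
  # permutation mass sits between the low observed values, so any negative
  # call admits false positives while the positive side stays clean
  null <- manual_null(rbind(c(0.6, 0.7, 0.8, 0.9, 1.0, 1.1),
                            c(0.6, 0.7, 0.8, 0.9, 1.9, 1.2)))
  got <- minimize_fdr_at_n(d, null, 1, 3)
  expect_equal(got$n_pos, 3L)
  expect_equal(got$n_neg, 0L)
  expect_equal(sort(got$feature_pos), c(4L, 5L, 6L))
})

test_that("precomputed one-sided counts equal a naive per-(k, b) recount", {
  for (seed in c(1, 2)) {
    inst <- rand_instance(M = 20, B = 3, seed = seed, ties = seed == 2)
    m_rho <- 12
    counts <- precompute_counts(inst$d, inst$null, m_rho)
    sd_ <- sort(inst$d)
    M <- length(inst$d)
    for (k in 0:m_rho) {
      tau_pos <- sd_[M - k]
      tau_neg <- sd_[k + 1]
      expect_equal(counts$tp_pos[k + 1], sum(inst$d > tau_pos))
      expect_equal(counts$tp_neg[k + 1], sum(inst$d < tau_neg))
      for (b in seq_len(inst$null$B)) {
        expect_equal(counts$fp_pos[k + 1, b], sum(inst$null$d_hat[b, ] > tau_pos))
        expect_equal(counts$fp_neg[k + 1, b], sum(inst$null$d_hat[b, ] < tau_neg))
      }
    }
    # distinct observed values make tp counts the order-statistic identity
    if (!anyDuplicated(inst$d)) {
      expect_equal(counts$tp_pos, 0:m_rho)
      expect_equal(counts$tp_neg, 0:m_rho)
    }
    # monotone in k
    expect_true(all(diff(counts$tp_pos) >= 0))
    expect_true(all(apply(counts$fp_pos, 2, function(x) all(diff(x) >= 0))))
  }
})

test_that("the compiled split scan agrees with the split-by-split estimator", {
  for (seed in 1:5) {
    inst <- rand_instance(M = 16, B = 4, seed = seed, ties = seed %% 2 == 0)
    counts <- precompute_counts(inst$d, inst$null, 10)
    curve <- mifdr:::min_fdr_curve(counts, inst$pi0, 10)
    for (k in 1:10) {
      ref <- minimize_fdr_at_n(inst$d, inst$null, inst$pi0, k)
      expect_equal(curve$est_fdr[k + 1], ref$fdr)
      expect_equal(curve$n_pos[k + 1], ref$n_pos)
    }
  }
})

test_that("the max-N search matches exhaustive brute force on small instances", {
  for (seed in 1:30) {
    inst <- rand_instance(M = 10 + seed %% 12, B = 2 + seed %% 4,
                          seed = seed, ties = seed %% 4 == 0)
    psi <- c(0.05, 0.15, 0.3, 0.6)[1 + seed %% 4]
    got <- max_features(inst$d, inst$null, inst$pi0, psi)
    ref <- oracle_max_features(inst$d, inst$null$d_hat, inst$pi0, psi)
    expect_equal(got$n_total, ref$n_total)
    if (ref$n_total > 0) {
      expect_equal(got$n_pos, ref$n_pos)
      expect_equal(got$fdr, ref$fdr)
      expect_lt(got$fdr, psi)
    } else {
      expect_false(got$found)
    }
  }
})

test_that("the max-N search is invariant to feature reordering", {
  inst <- rand_instance(M = 18, B = 4, seed = 77)
  got <- max_features(inst$d, inst$null, inst$pi0, 0.3)
  set.seed(1)
  perm <- sample(18)
  null_p <- manual_null(inst$null$d_hat[, perm, drop = FALSE])
  got_p <- max_features(inst$d[perm], null_p, inst$pi0, 0.3)
  expect_equal(got_p$n_total, got$n_total)
  expect_equal(got_p$n_pos, got$n_pos)
  expect_equal(got_p$fdr, got$fdr)
  # the called features are the same ones, relabelled by the permutation
  expect_setequal(perm[got_p$feature_pos], got$feature_pos)
})

test_that("a self-null instance yields no qualifying call set at small psi", {
  d <- c(-2, -1, 0, 1, 2)
  null <- manual_null(rbind(d, d, d))
  got <- max_features(d, null, pi0 = 1, psi = 0.4)
  expect_false(got$found)
  expect_equal(got$n_total, 0L)
})

test_that("the end-to-end fit wrapper ties the stages together", {
  ds <- make_dataset(M = 40, nx = 4, ny = 4, seed = 5, shift = 4)
  fit <- mifdr(ds, mode = "fixed_n", n = 2, B = 20, seed = 11)
  expect_s3_class(fit, "mifdr_fit")
  g <- glance(fit)
  expect_equal(g$n_called, 2L)
  td <- tidy(fit)
  expect_equal(nrow(td), 40L)
  expect_equal(sum(td$called), 2L)
  # the same seed reproduces the fit exactly
  fit2 <- mifdr(ds, mode = "fixed_n", n = 2, B = 20, seed = 11)
  expect_equal(glance(fit2), g)
  expect_s3_class(autoplot(fit), "ggplot")
})
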