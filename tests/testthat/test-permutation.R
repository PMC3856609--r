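test_that("the null is bit-reproducible from its seed", {
  ds <- make_dataset(M = 10, nx = 4, ny = 4, seed = 2)
  a <- permutation_null(ds, "t", B = 20, seed = 123)
  b <- permutation_null(ds, "t", B = 20, seed = 123)
  expect_identical(a$d_hat, b$d_hat)
  expect_identical(a$expected_order_stats, b$expected_order_stats)
  c <- permutation_null(ds, "t", B = 20, seed = 124)
  expect_false(identical(a$d_hat, c$d_hat))
})

test_that("exhaustive mode enumerates exactly the distinct labelings (2 vs 2)", {
  vals <- matrix(c(1.2, -0.7, 0.3, 2.1,
                   0.5, 0.9, -1.4, 0.2), nrow = 2, byrow = TRUE)
  ds <- expression_dataset(vals, labels = c("X", "X", "Y", "Y"))
  comp <- t_components(ds)
  s0 <- 0.1
  null <- permutation_null(ds, "t", B = 6, seed = 1, s0 = s0, mode = "exhaustive")
  expect_equal(null$B, choose(4, 2))

  # hand enumeration: every choice of which 2 samples form group X
  hand <- t(sapply(utils::combn(4, 2, simplify = FALSE), function(ix) {
    iy <- setdiff(1:4, ix)
    sapply(1:2, function(i) {
      x <- vals[i, ix]; y <- vals[i, iy]
      r <- mean(x) - mean(y)
      s <- sqrt((sum((x - mean(x))^2) + sum((y - mean(y))^2)) * (1/2 + 1/2) / 2)
      r / (s + s0)
    })
  }))
  expect_equal(null$d_hat[order(null$d_hat[, 1]), ],
               hand[order(hand[, 1]), ], ignore_attr = TRUE)

  expect_error(permutation_null(ds, "t", B = 10, seed = 1, mode = "exhaustive"),
               "exceeds")
})

test_that("sorted permutation rows and expected order statistics are nondecreasing", {
  for (seed in 1:3) {
    ds <- make_dataset(M = 15, nx = 3, ny = 5, seed = seed)
    null <- permutation_null(ds, "t", B = 25, seed = seed)
    expect_true(all(apply(null$sorted_d_hat, 1, function(x) all(diff(x) >= 0))))
    expect_true(all(diff(null$expected_order_stats) >= 0))
  }
})

test_that("the supplied s0 is reused for all permutations", {
  ds <- make_dataset(M = 8, nx = 3, ny = 3, seed = 4)
  null <- permutation_null(ds, "t", B = 10, seed = 9, s0 = 0.5)
  expect_equal(null$s0, 0.5)
  # recompute one row by hand with that s0
  set.seed(9)
  # row values must equal d-values of some 3-of-6 labeling at s0 = 0.5
  all_d <- t(sapply(utils::combn(6, 3, simplify = FALSE), function(ix) {
    iy <- setdiff(1:6, ix)
    sapply(1:8, function(i) {
      x <- ds$values[i, ix]; y <- ds$values[i, iy]
      r <- mean(x) - mean(y)
      s <- sqrt((sum((x - mean(x))^2) + sum((y - mean(y))^2)) * (2/3) / 4)
      r / (s + 0.5)
    })
  }))
  for (b in seq_len(null$B)) {
    gaps <- apply(all_d, 1, function(row) max(abs(row - null$d_hat[b, ])))
    expect_lt(min(gaps), 1e-12)
  }
})

test_that("pi0 follows the quantile-window arithmetic", {
  # pooled permuted values with quartiles at -1 and 1 (type-7 interpolation)
  null <- manual_null(matrix(seq(-2, 2, length.out = 101), nrow = 1))
  qs <- quantile(null$d_hat, c(0.25, 0.75))
  expect_equal(unname(qs), c(-1, 1))

  # half the observed values inside the window -> pi0 = 1
  d_half <- c(-0.5, 0.5, 3, -3, 0.1, -0.1, 5, -5)
  expect_equal(estimate_pi0(d_half, null)$pi0, 1)

  # all observed far outside -> floored at 1/M, never exactly 0
  d_out <- c(10, -10, 20, -20)
  expect_equal(estimate_pi0(d_out, null)$pi0, 1 / 4)

  # window is configurable
  est <- estimate_pi0(d_half, null, window = c(0.1, 0.9))
  expect_equal(est$window, c(0.1, 0.9))
  expect_error(estimate_pi0(d_half, null, window = c(0.9, 0.1)), "increasing")
})

test_that("pi0 is near 1 on pure-null data", {
  sc <- simulation_scenario(
    data.frame(n_features = 10000L, dist1 = "normal", a1 = 0, b1 = 1,
               dist2 = "normal", a2 = 0, b2 = 1, alternative = FALSE),
    n_per_group = 8L
  )
  sim <- simulate_dataset(sc, seed = 31)
  stats <- d_statistics(sim$dataset, "t")
  null <- permutation_null(sim$dataset, "t", B = 30, seed = 32, s0 = stats$s0)
  pi0 <- estimate_pi0(stats$d, null)$pi0
  expect_gte(pi0, 0.8)
  expect_lte(pi0, 1)
})

test_that("delta-values behave as gaps to the expected order statistics", {
  null <- manual_null(rbind(c(-2, -1, 0, 1, 2), c(-2, -1, 0, 1, 2)))
  d <- c(0, -1, 2, 1, -2)  # identical set, any order
  expect_equal(delta_values(d, null), rep(0, 5))

  # translation equivariance
  expect_equal(delta_values(d + 0.3, null), rep(0.3, 5))

  # one outlying permuted column makes delta non-monotone in d
  null2 <- manual_null(rbind(c(-1, 0, 0, 0, 12), c(-1, 0, 0, 0, 12)))
  delta <- delta_values(c(1, 2, 3, 4, 5), null2)
  expect_true(any(diff(delta) < 0))
})
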