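test_that("t components match the pooled-variance closed form", {
  ds <- expression_dataset(matrix(c(1, 3, 2, 4), nrow = 1),
                           labels = c("X", "X", "Y", "Y"))
  comp <- t_components(ds)
  expect_equal(comp$r, -1)            # mean(1,3) - mean(2,4)
  expect_equal(comp$s, sqrt(2))       # sqrt((2+2) * (1/2+1/2) / 2)

  # constant feature: zero difference, zero spread
  dsc <- expression_dataset(matrix(7, nrow = 1, ncol = 4),
                            labels = c("X", "X", "Y", "Y"))
  compc <- t_components(dsc)
  expect_equal(compc$r, 0)
  expect_equal(compc$s, 0)
})

test_that("ranksum components match the rank-sum closed form and are rank-invariant", {
  ds <- expression_dataset(matrix(c(1, 2, 3, 4), nrow = 1),
                           labels = c("X", "X", "Y", "Y"))
  comp <- ranksum_components(ds)
  expect_equal(comp$r, -2)                 # ranks of X = {1,2}; 3 - 2*5/2
  expect_equal(comp$s, sqrt(2 * 2 * 5 / 12))

  # identical multisets across groups with average-rank ties -> r = 0
  dst <- expression_dataset(matrix(c(5, 9, 5, 9), nrow = 1),
                            labels = c("X", "X", "Y", "Y"))
  expect_equal(ranksum_components(dst)$r, 0)

  # strictly monotone transform leaves (r, s) unchanged
  ds2 <- make_dataset(M = 5, nx = 3, ny = 4, seed = 11)
  ds3 <- ds2; ds3$values <- exp(ds2$values)
  expect_equal(ranksum_components(ds2), ranksum_components(ds3))
})

test_that("swapping group labels negates r and d and leaves s, s0 unchanged", {
  for (seed in 1:3) {
    ds <- make_dataset(M = 12, nx = 3, ny = 4, seed = seed, shift = 1)
    # list group B's samples first so it becomes group X
    ord <- order(ds$labels == ds$groups[1])
    flipped <- expression_dataset(ds$values[, ord],
                                  labels = as.character(ds$labels)[ord])
    for (stat in c("t", "ranksum")) {
      a <- d_statistics(ds, stat)
      b <- d_statistics(flipped, stat)
      expect_equal(b$r, -a$r)
      expect_equal(b$s, a$s)
      expect_equal(b$s0, a$s0)
      expect_equal(b$d, -a$d)
    }
  }
})

test_that("s0 selection equals an exhaustive scan of its candidate pool", {
  # printed toy: candidates {0, 1, 10}
  r <- c(1, 10); s <- c(1, 10)
  cand <- c(0, 1, 10)
  expect_equal(select_s0(r, s, candidates = cand),
               oracle_s0(r, s, candidates = sort(unique(c(0, cand)))))

  # random instances, both the full unique-s pool and the default grid
  for (seed in 1:5) {
    set.seed(seed)
    r <- rnorm(10); s <- abs(rnorm(10))
    pool <- sort(unique(c(0, s)))
    expect_equal(select_s0(r, s, candidates = s), oracle_s0(r, s, pool))
    default_pool <- sort(unique(c(0, quantile(s, seq(0, 1, 0.05), type = 1))))
    expect_equal(select_s0(r, s), oracle_s0(r, s, default_pool))
  }

  # all spreads equal: every candidate ties, smallest (0) wins
  expect_equal(select_s0(c(1, -2, 3), rep(2, 3)), 0)

  # degenerate: all s zero with a nonzero difference
  expect_error(select_s0(c(1, 0), c(0, 0)), "degenerate spread")
  # all s and r zero is fine: s0 = 0, d = 0
  expect_equal(select_s0(c(0, 0), c(0, 0)), 0)
})

test_that("s0 selection is scale-equivariant so d is scale-invariant (t form)", {
  set.seed(42)
  r <- rnorm(30); s <- abs(rnorm(30)) + 0.1
  k <- 3.7
  s0a <- select_s0(r, s)
  s0b <- select_s0(k * r, k * s)
  expect_equal(s0b, k * s0a)
  expect_equal(d_values(k * r, k * s, s0b), d_values(r, s, s0a))
})

test_that("d-values are the exact ratio with no clipping", {
  expect_equal(d_values(c(0, 0), c(1, 2), 0.5), c(0, 0))
  expect_equal(d_values(c(1, -2), c(1, 1), 1), c(0.5, -1))
  # monotone shrinkage in s0
  expect_equal(d_values(1, 1, 1), 0.5)
  expect_equal(d_values(1, 1, 2), 1 / 3)
  expect_error(d_values(1, 0, 0), "degenerate spread")
})

test_that("t p-values match an independent t-CDF evaluation", {
  ds <- expression_dataset(matrix(c(1, 3, 2, 4), nrow = 1),
                           labels = c("X", "X", "Y", "Y"))
  p <- feature_pvalues(ds, "t_two_sided")
  expect_equal(p, 2 * pt(-abs(-1 / sqrt(2)), df = 2))

  # identical groups: zero statistic, p = 1
  dsi <- expression_dataset(matrix(c(1, 2, 3, 1, 2, 3), nrow = 1),
                            labels = rep(c("X", "Y"), each = 3))
  expect_equal(feature_pvalues(dsi, "t_two_sided"), 1)

  # random features against stats::t.test
  ds2 <- make_dataset(M = 8, nx = 4, ny = 5, seed = 9)
  p2 <- feature_pvalues(ds2, "t_two_sided")
  idx <- mifdr:::group_indices(ds2)
  for (i in seq_len(8)) {
    ref <- t.test(ds2$values[i, idx$x], ds2$values[i, idx$y],
                  var.equal = TRUE)$p.value
    expect_equal(p2[i], ref)
  }

  # one-sided never exceeds two-sided in the favored direction
  comp <- t_components(ds2)
  p1 <- feature_pvalues(ds2, "t_one_sided")
  up <- comp$r > 0
  expect_true(all(p1[up] <= p2[up] + 1e-12))
})

test_that("ranksum p-values match the tie-corrected normal approximation", {
  ds <- make_dataset(M = 6, nx = 4, ny = 4, seed = 3)
  ds$values[2, ] <- round(ds$values[2, ])  # force ties
  p <- feature_pvalues(ds, "ranksum_two_sided")
  idx <- mifdr:::group_indices(ds)
  for (i in seq_len(6)) {
    ref <- suppressWarnings(
      wilcox.test(ds$values[i, idx$x], ds$values[i, idx$y],
                  exact = FALSE, correct = FALSE)$p.value
    )
    expect_equal(p[i], ref)
  }
})
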