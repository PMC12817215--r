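test_that("error matrices carry absolute errors and direction flags", {
  pred <- matrix(c(0, 5, 0, 0), 2, 2, byrow = TRUE)
  obs <- matrix(c(0, 3, 7, 0), 2, 2, byrow = TRUE)
  e <- error_matrix(pred, obs)
  expect_equal(e$abs, abs(pred - obs))
  expect_equal(e$sign[1, 2], 1)   # over
  expect_equal(e$sign[2, 1], -1)  # under
  expect_true(all(e$abs[e$sign == 0] == 0))
  expect_error(error_matrix(pred, matrix(0, 3, 3)), "shape")
})

test_that("Hamming distance counts nonzero cells; tallies partition the off-diagonal", {
  expect_equal(hamming_distance(matrix(0, 4, 4)), 0)
  E <- matrix(0, 4, 4); E[1, 2] <- 3; E[3, 4] <- 1; E[2, 1] <- 2
  expect_equal(hamming_distance(E), 3)
  pred <- matrix(5, 4, 4); diag(pred) <- 0
  obs <- pred; obs[1, 2] <- 3; obs[2, 1] <- 9
  tl <- estimation_tally(pred, obs)
  expect_equal(unname(tl), c(1, 10, 1))
  expect_equal(sum(tl), 4 * 3)
  # complement identity: H = L^2 - (#correct cells including the diagonal)
  H <- hamming_distance(error_matrix(pred, obs)$abs)
  expect_equal(H, 16 - (tl[["correct"]] + 4))
})

test_that("one-sided Mann-Whitney follows the mid-p exact convention", {
  # identical samples: symmetric permutation distribution -> p = 1/2
  expect_equal(mann_whitney_one_sided(c(1, 2, 3), c(1, 2, 3))$p.value, 0.5)
  mw <- mann_whitney_one_sided(c(0, 0, 1), c(5, 6, 7))
  expect_equal(mw$statistic, 0)           # every modified error smaller
  expect_lte(mw$p.value, 0.05)
  # independent brute-force oracle: enumerate all 20 assignments directly
  pooled <- c(0, 0, 1, 5, 6, 7); r <- rank(pooled)
  U_all <- apply(utils::combn(6, 3), 2, function(ix) sum(r[ix]) - 6)
  u_obs <- sum(r[1:3]) - 6
  p_oracle <- (sum(U_all < u_obs) + 0.5 * sum(U_all == u_obs)) / length(U_all)
  expect_equal(mw$p.value, p_oracle)
})

test_that("joint-zero filtering drops exactly the jointly-zero cells", {
  x <- c(0, 0, 2, 0, 1); y <- c(0, 3, 0, 0, 1)
  mw <- mann_whitney_one_sided(x, y, drop_joint_zeros = TRUE)
  expect_equal(mw$dropped, 2L)
  expect_equal(mw$n1, 3L)
  expect_error(mann_whitney_one_sided(c(0, 0), c(0, 0), drop_joint_zeros = TRUE),
               "empty")
})

test_that("exact enumeration and the normal approximation agree for joint sizes 15-20", {
  set.seed(77)
  worst_free <- 0
  for (r in 1:30) {
    n1 <- sample(7:10, 1); n2 <- sample(8:10, 1)
    x <- runif(n1); y <- runif(n2)          # tie-free
    pe <- mann_whitney_one_sided(x, y, exact = TRUE)$p.value
    pa <- mann_whitney_one_sided(x, y, exact = FALSE)$p.value
    worst_free <- max(worst_free, abs(pe - pa))
  }
  expect_lt(worst_free, 0.01)               # two-decimal agreement
  # heavy ties put the p-values on a coarse lattice; agreement degrades
  # gracefully but stays within the lattice step
  worst_tied <- 0
  for (r in 1:30) {
    x <- rpois(sample(7:10, 1), 2); y <- rpois(sample(8:10, 1), 2)
    pe <- mann_whitney_one_sided(x, y, exact = TRUE)$p.value
    pa <- mann_whitney_one_sided(x, y, exact = FALSE)$p.value
    worst_tied <- max(worst_tied, abs(pe - pa))
  }
  expect_lt(worst_tied, 0.06)
})

test_that("the one-sided direction matches an independent implementation", {
  set.seed(5)
  for (r in 1:10) {
    x <- rpois(40, 1); y <- rpois(45, 2)
    p <- mann_whitney_one_sided(x, y)$p.value
    pw <- suppressWarnings(stats::wilcox.test(x, y, alternative = "less")$p.value)
    # same convention up to the continuity correction: ordering and scale agree
    expect_equal(p, pw, tolerance = 0.02)
    expect_lt(p, 0.5)
  }
})

test_that("binomial Hamming test matches a log-space summation oracle", {
  log_oracle <- function(h_mod, h_std, L) {
    n <- L^2; p <- h_std / n
    sum(exp(stats::dbinom(0:h_mod, n, p, log = TRUE)))
  }
  expect_equal(binomial_hamming_test(5, 10, 10)$p.value, log_oracle(5, 10, 10),
               tolerance = 1e-12)
  set.seed(8)
  for (r in 1:20) {
    L <- sample(5:100, 1)
    h_std <- sample(L^2, 1)   # h_std = 0 follows its own degenerate convention
    h_mod <- sample(0:L^2, 1)
    expect_equal(binomial_hamming_test(h_mod, h_std, L)$p.value,
                 log_oracle(h_mod, h_std, L), tolerance = 1e-12)
  }
  # equal Hamming distances sit at the binomial mean: CDF >= 1/2
  expect_gt(binomial_hamming_test(40, 40, 20)$p.value, 0.5)
  # perfect modified model: single surviving term (1 - p_hat)^(L^2)
  expect_equal(binomial_hamming_test(0, 7, 8)$p.value, (1 - 7 / 64)^64)
  # degenerate reference
  expect_equal(binomial_hamming_test(3, 0, 5)$p.value, 0)
  expect_equal(binomial_hamming_test(0, 0, 5)$p.value, 1)
})

test_that("permutation nulls are reproducible and quantiles sensible", {
  locs <- random_system(L = 12, pop_max = 5000, seed = 31)
  od <- generate_od(locs, "two_class", delta = 1.001, seed = 32)
  a <- permutation_null(od$observed, locs, scheme = c(1, 1.001),
                        model = "two_class", n_reps = 30, seed = 5)
  b <- permutation_null(od$observed, locs, scheme = c(1, 1.001),
                        model = "two_class", n_reps = 30, seed = 5)
  expect_identical(a, b)
  expect_lte(a$q5_U, max(a$U))
  expect_lte(sum(a$U < a$q5_U), ceiling(0.05 * 30))
  expect_warning(
    permutation_null(od$observed, locs, scheme = c(1, 1.001),
                     model = "two_class", n_reps = 10, seed = 5),
    "unreliable")
})

test_that("compare_models detects a strong true signal end to end", {
  locs <- random_system(L = 20, pop_max = 1e5, seed = 41, frac = 0.2)
  od <- generate_od(locs, "two_class", delta = 1 + 1e-4, seed = 42)
  cmp <- compare_models(od$observed, locs, scheme = c(1, 1 + 1e-4),
                        model = "two_class", n_reps = 60, seed = 43)
  expect_true(cmp$verdict)
  expect_lt(cmp$mw$p.value, 0.05)
  expect_lt(cmp$hamming$mod, cmp$hamming$std)
  expect_output(print(cmp), "outperforms")
})
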