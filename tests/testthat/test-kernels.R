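test_that("standard radiation probability matches direct arithmetic", {
  expect_equal(radiation_probability(1, 1, 0), 0.5)
  expect_equal(radiation_probability(2, 3, 5), 6 / 70)
  # two-city system: p12 = n2/(n1+n2), p21 = n1/(n1+n2)
  n1 <- 1e4; n2 <- 1e6
  expect_equal(radiation_probability(n1, n2, 0), n2 / (n1 + n2))
  expect_equal(radiation_probability(n2, n1, 0), n1 / (n1 + n2))
  expect_error(radiation_probability(0, 1, 0), "populations")
})

test_that("two-class closed forms evaluate the printed cases", {
  # delta = 1 recovers the standard model for every case
  for (oc in 1:2) for (dc in 1:2)
    expect_equal(modified_probability_two_class(2, 3, 2, 3, oc, dc, 1),
                 radiation_probability(2, 3, 5), tolerance = 1e-14)
  # 2 -> 2 picks up delta^(-s1)
  expect_equal(modified_probability_two_class(4, 5, 3, 2, 2, 2, 2),
               radiation_probability(4, 5, 5) / 8)
  # 2 -> 1 with m=2, n=1, s=0, delta=2: (1/3) * [1 + 2 (1 - 1/2)] = 2/3
  expect_equal(modified_probability_two_class(2, 1, 0, 0, 2, 1, 2), 2 / 3)
  # 1 -> 1 three-term bracket sums to 1 at delta = 1
  expect_equal(modified_probability_two_class(1, 1, 1, 1, 1, 1, 1),
               radiation_probability(1, 1, 2))
  expect_error(modified_probability_two_class(1, 1, 0, 0, 1, 1, 0), "delta")
})

test_that("large exponents are handled in log space without overflow", {
  p <- modified_probability_two_class(1e6, 5e5, 2e5, 3e5, 2, 1, 1 + 1e-4)
  expect_true(is.finite(p) && p >= 0)
  p2 <- modified_probability_two_class(1e6, 5e5, 2e5, 3e5, 1, 2, 1 + 1e-4)
  expect_true(is.finite(p2) && p2 >= 0)
})

test_that("integral engine agrees with the closed forms across delta in [0.5, 3]", {
  set.seed(101)
  worst <- 0
  for (r in 1:1000) {
    m <- sample(50, 1); n <- sample(50, 1)
    s1 <- sample(0:100, 1); s2 <- sample(0:100, 1)
    oc <- sample(2, 1); dc <- sample(2, 1)
    d <- runif(1, 0.5, 3)
    a <- modified_probability_two_class(m, n, s1, s2, oc, dc, d)
    b <- general_probability_integral(m, n, c(s1, s2), oc, dc, c(1, d))
    worst <- max(worst, abs(a - b) / max(abs(a), 1e-300))
  }
  expect_lt(worst, 1e-8)
})

test_that("integral engine: homogeneous case and class-merging consistency", {
  expect_equal(general_probability_integral(7, 9, 12, 1, 1, 1),
               radiation_probability(7, 9, 12), tolerance = 1e-14)
  # three classes with equal deltas collapse to the merged two-class result
  a <- general_probability_integral(10, 20, c(5, 7, 11), 1, 3, c(1, 1.7, 1.7))
  b <- modified_probability_two_class(10, 20, 5, 18, 1, 2, 1.7)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("linearized slopes at delta = 1 match the nonlinear derivatives", {
  eps <- 1e-5
  m <- 7; n <- 9; s1 <- 4; s2 <- 6
  rho <- c("21" = m + s2, "22" = -s1, "12" = -(m + s1), "11" = s2)
  for (k in names(rho)) {
    oc <- as.integer(substr(k, 1, 1)); dc <- as.integer(substr(k, 2, 2))
    f <- function(d) modified_probability_two_class(m, n, s1, s2, oc, dc, d)
    # right-sided Richardson difference: the model is C1 but not C2 at
    # delta = 1 (the saturation regime flips), so central differences stall
    num <- (4 * f(1 + eps) - 3 * f(1) - f(1 + 2 * eps)) / (2 * eps)
    expect_equal(num / radiation_probability(m, n, s1 + s2), unname(rho[k]),
                 tolerance = 1e-4)
    lin <- linearized_probability(m, n, c(s1, s2), oc, dc, c(1, 1 + eps))
    expect_equal(lin, radiation_probability(m, n, s1 + s2) * (1 + rho[[k]] * eps),
                 tolerance = 1e-12)
  }
})

test_that("linearization error is second order in (delta - 1)", {
  set.seed(33)
  for (r in 1:20) {
    m <- sample(30, 1); n <- sample(30, 1)
    s1 <- sample(0:40, 1); s2 <- sample(0:40, 1)
    oc <- sample(2, 1); dc <- sample(2, 1)
    ratios <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
      a <- modified_probability_two_class(m, n, s1, s2, oc, dc, 1 + eps)
      b <- suppressWarnings(
        linearized_probability(m, n, c(s1, s2), oc, dc, c(1, 1 + eps)))
      abs(a - b) / eps^2
    }, numeric(1))
    # bounded (non-exploding) as delta -> 1; scale set by the coarsest epsilon
    expect_lt(max(ratios), 10 * max(ratios[1], 1))
  }
})

test_that("negative linearized probabilities are clipped with a warning", {
  expect_warning(
    p <- linearized_probability(100, 5, c(50, 0), 1, 2, c(1, 1.5), warn_band = 1),
    "clipped")
  expect_identical(p, 0)
})

test_that("2->2 probability is non-increasing in delta >= 1", {
  ds <- seq(1, 5, length.out = 50)
  p <- modified_probability_two_class(10, 20, 15, 5, 2, 2, ds)
  expect_true(all(diff(p) <= 1e-15))
})
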