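test_that("standard matrix for two locations normalizes to a swap matrix", {
  locs <- data.frame(id = c("a", "b"), x_km = c(0, 10), y_km = 0,
                     population = c(100, 7))
  P <- build_probability_matrix(locs, model = "standard")
  expect_equal(unname(P), matrix(c(0, 1, 1, 0), 2, 2), ignore_attr = TRUE)
})

test_that("every variant reduces to the standard model at delta = 1", {
  locs <- random_system(L = 12, seed = 8)
  P0 <- build_probability_matrix(locs, model = "standard")
  for (v in c("two_class", "linearized", "integral")) {
    P <- build_probability_matrix(locs, c(1, 1), v)
    expect_lt(max(abs(P - P0)), 1e-12)
  }
})

test_that("two-class closed-form matrix matches the integral engine entrywise", {
  for (dd in c(0.7, 1.8)) {
    locs <- random_system(L = 10, seed = 21)
    P1 <- build_probability_matrix(locs, c(1, dd), "two_class")
    P2 <- build_probability_matrix(locs, c(1, dd), "integral")
    expect_lt(max(abs(P1 - P2)), 1e-8)
    expect_rows_normalized(P1)
    expect_rows_normalized(P2)
  }
})

test_that("linearized multi-class matrix matches the integral engine to first order", {
  locs <- random_system(L = 10, seed = 13)
  # three classes with small per-class perturbations
  locs$class <- rep_len(1:3, nrow(locs))
  # keep max(s_ij * eps) well under 1 so second-order terms are truly small
  eps <- c(0, 1e-5, 1.7e-5)
  Plin <- build_probability_matrix(locs, 1 + eps, "linearized")
  Pint <- build_probability_matrix(locs, 1 + eps, "integral")
  P0 <- build_probability_matrix(locs, c(1, 1, 1), "standard")
  # discrepancy must be second order: much smaller than the first-order shift
  shift <- max(abs(Pint - P0))
  expect_gt(shift, 0)
  expect_lt(max(abs(Plin - Pint)), 0.02 * shift)
})

test_that("two_class model demands exactly two classes", {
  locs <- random_system(L = 8, seed = 2)
  locs$class <- 1L
  expect_error(build_probability_matrix(locs, 1, "two_class"), "exactly 2")
})

test_that("predict_fluxes conserves totals and rounds half away from zero", {
  locs <- random_system(L = 8, seed = 4)
  P <- build_probability_matrix(locs, model = "standard")
  T_i <- c(0, rep(100, 7))
  raw <- predict_fluxes(P, T_i, round_to_int = FALSE)
  expect_true(all(raw[1, ] == 0))                       # zero outflow row
  expect_equal(unname(rowSums(raw)), T_i, tolerance = 1e-9)  # conservation
  P1 <- matrix(c(0, 0.333, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(predict_fluxes(P1, c(100, 10))[1, 2], 33)
  expect_equal(predict_fluxes(matrix(c(0, 0.5, 1, 0), 2, 2, byrow = TRUE),
                              c(1, 0))[1, 2], 1)        # .5 rounds away from zero
  expect_error(predict_fluxes(P1, c(-1, 5)), "outflow")
})

test_that("mobile fraction is the no-intercept regression slope", {
  locs <- random_system(L = 10, seed = 9)
  pop <- locs$population
  expect_equal(estimate_mobile_fraction(0.1 * pop, locs), 0.1)
  set.seed(1)
  noise <- rnorm(10, 0, 0.01) * pop
  est <- estimate_mobile_fraction(0.1 * pop + noise, locs)
  expect_equal(est, sum(pop * (0.1 * pop + noise)) / sum(pop^2))
  expect_equal(est, 0.1, tolerance = 0.05)
  expect_equal(estimate_mobile_fraction(5, 50), 0.1)    # single location
})
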