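# Small fixtures built in code.

# collinear planar system: origin i at 0, A (pop 7, class 1) at 1 km,
# destination j (pop 4, class 2) at 2 km, B (pop 9, class 2) at 3 km
line_system <- function() {
  data.frame(id = c("i", "A", "j", "B"),
             x_km = c(0, 1, 2, 3), y_km = 0,
             population = c(2, 7, 4, 9),
             class = c(1L, 1L, 2L, 2L))
}

# random planar two-class system with modest populations
random_system <- function(L, pop_max = 500, seed = NULL, frac = 0.2) {
  generate_system(L = L, pop_max = pop_max, seed = seed,
                  penalized_fraction = frac)
}

expect_rows_normalized <- function(P, tol = 1e-12) {
  rs <- rowSums(P)
  expect_true(all(abs(rs[rs > 0] - 1) < tol))
  expect_true(all(diag(P) == 0))
}
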