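# Model-comparison protocol: absolute-error matrices, one-sided Mann-Whitney,
# Hamming distance with a binomial significance test, and permutation nulls
# obtained by randomly reassigning location classes with fixed class sizes.

#' Absolute-error matrix with over/correct/under flags
#'
#' @param pred,obs integer OD flux matrices on the same location set.
#' @return List with `abs` (|pred - obs|) and `sign` (sign(pred - obs):
#'   +1 over-, 0 correct, -1 under-estimated).
#' @export
error_matrix <- function(pred, obs) {
  if (!all(dim(pred) == dim(obs))) stop("prediction and observation shapes differ")
  list(abs = abs(pred - obs), sign = sign(pred - obs))
}

#' Hamming distance of an error matrix
#'
#' Number of nonzero cells — a sparsity-structure agreement measure suited to
#' flux matrices where most entries are zero.
#'
#' @param errors an [error_matrix()] result or a plain matrix of errors.
#' @return Integer count.
#' @export
hamming_distance <- function(errors) {
  E <- if (is.list(errors)) errors$abs else abs(errors)
  sum(E > 0)
}

#' Over/correct/under estimation tally
#'
#' Counts, over the off-diagonal cells (both models force zero diagonal
#' fluxes, so diagonal cells carry no information), how many fluxes the
#' prediction overestimates, estimates exactly, and underestimates.
#'
#' @param pred,obs integer OD flux matrices.
#' @return Named integer vector `c(over, correct, under)`.
#' @export
estimation_tally <- function(pred, obs) {
  off <- row(pred) != col(pred)
  d <- (pred - obs)[off]
  c(over = sum(d > 0), correct = sum(d == 0), under = sum(d < 0))
}

# rank-based U statistic for sample x against y: number of (x, y) pairs with
# x > y, ties counting one half
mw_u_statistic <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

# exact one-sided mid-p by enumeration of all assignments of the pooled
# values to the first sample: p = P(U < u) + P(U = u)/2
mw_exact_midp <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  combs <- utils::combn(length(pooled), n1)
  offset <- n1 * (n1 + 1) / 2
  U <- colSums(matrix(r[combs], nrow = n1)) - offset
  u_obs <- sum(r[seq_len(n1)]) - offset
  (sum(U < u_obs - 1e-9) + 0.5 * sum(abs(U - u_obs) < 1e-9)) / length(U)
}

#' One-sided Mann-Whitney test for smaller errors
#'
#' Tests the alternative that the first error sample (the modified model's)
#' is stochastically smaller than the second (the standard model's). For a
#' joint sample size of at most 20 the mid-p value is computed by exact
#' enumeration over all assignments; otherwise a tie-corrected normal
#' approximation (without continuity correction, matching the mid-p
#' convention) is used. Identical samples give p = 0.5.
#'
#' @param errors_mod,errors_std flat error samples, cell-aligned when
#'   `drop_joint_zeros` is used.
#' @param drop_joint_zeros remove cells where BOTH errors are zero before
#'   testing (used when the vast majority of fluxes are zero and correctly
#'   predicted by both models).
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` decides by joint size <= 20.
#' @return List with `statistic` (U of the modified sample), `p.value`,
#'   sample sizes and the number of jointly-zero cells dropped.
#' @export
mann_whitney_one_sided <- function(errors_mod, errors_std,
                                   drop_joint_zeros = FALSE, exact = NULL) {
  dropped <- 0L
  if (drop_joint_zeros) {
    if (length(errors_mod) != length(errors_std))
      stop("joint-zero filtering requires cell-aligned samples")
    keep <- !(errors_mod == 0 & errors_std == 0)
    dropped <- sum(!keep)
    errors_mod <- errors_mod[keep]
    errors_std <- errors_std[keep]
  }
  n1 <- length(errors_mod); n2 <- length(errors_std)
  if (n1 == 0 || n2 == 0) stop("empty sample after filtering")
  U <- mw_u_statistic(errors_mod, errors_std)
  N <- n1 + n2
  if (is.null(exact)) exact <- N <= 20
  if (exact) {
    p <- mw_exact_midp(errors_mod, errors_std)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(c(errors_mod, errors_std))
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    p <- if (sig2 <= 0) 0.5 else stats::pnorm((U - mu) / sqrt(sig2))
  }
  list(statistic = U, p.value = p, n1 = n1, n2 = n2, dropped = dropped)
}

#' Binomial significance test on Hamming distances
#'
#' Models the Hamming distance as a Binomial(L^2, p) draw with success
#' probability estimated from the standard model, `p_hat = H_std / L^2`, and
#' returns the exact lower-tail probability `P(Binomial(L^2, p_hat) <= H_mod)`
#' — small values mean the modified model's error matrix is significantly
#' sparser than the standard model's.
#'
#' @param h_mod,h_std Hamming distances of the modified and standard models.
#' @param L number of locations.
#' @return List with `p.value`, `p_hat` and `trials`.
#' @export
binomial_hamming_test <- function(h_mod, h_std, L) {
  n <- L^2
  if (h_mod < 0 || h_mod > n || h_std < 0 || h_std > n)
    stop("Hamming distances must lie in [0, L^2]")
  p_hat <- h_std / n
  p <- if (p_hat == 0) {
    if (h_mod > 0) 0 else 1   # degenerate reference model with zero errors
  } else {
    stats::pbinom(h_mod, n, p_hat)
  }
  list(p.value = p, p_hat = p_hat, trials = n)
}

# Precomputed context for repeated modified-model builds under reassigned
# classes: everything that does not depend on the class labels.
comparison_context <- function(locations, distances) {
  neigh <- neighbor_structure(distances)
  pop <- locations$population
  S <- intervening_weighted(neigh, pop)
  list(locations = locations, pop = pop, neigh = neigh, S = S,
       P_std = row_normalize(standard_matrix(pop, S)))
}

# Modified probability matrix for an arbitrary class assignment, reusing the
# context. For "two_class", `assignment` is the class vector and scheme[2]
# the penalty; for "linearized", `assignment` is the per-location delta.
modified_P_for <- function(ctx, model, assignment, scheme = NULL) {
  if (model == "two_class") {
    S2 <- intervening_weighted(ctx$neigh, ctx$pop * (assignment == 2L))
    P <- two_class_matrix(ctx$pop, assignment, scheme[2], ctx$S, S2)
  } else {
    W <- intervening_weighted(ctx$neigh, ctx$pop * (assignment - 1))
    P <- linearized_matrix(ctx$pop, assignment, ctx$S, W)
  }
  row_normalize(P)
}

#' Permutation null distributions under random class reassignment
#'
#' Re-runs the modified model `n_reps` times with classes assigned uniformly
#' at random while keeping the class sizes fixed, and records the
#' Mann-Whitney U statistic (against the standard model's errors) and the
#' Hamming distance of each null replicate. The 5% empirical quantiles are
#' the pass thresholds for the nonparametric comparison: the observed
#' statistic must fall below them.
#'
#' @param observed observed OD flux matrix.
#' @param locations location table with the class column (or, for
#'   `model = "linearized"`, with per-location deltas supplied via `delta_loc`).
#' @param scheme per-class deltas (two-class model).
#' @param delta_loc per-location deltas (linearized model).
#' @param model `"two_class"` or `"linearized"`.
#' @param outflow totals T_i; defaults to the observed off-diagonal row sums.
#' @param n_reps number of null replicates (1000 for binary schemes, 200 for
#'   ramp schemes in the reference protocol).
#' @param seed RNG seed.
#' @param drop_joint_zeros passed to [mann_whitney_one_sided()].
#' @return List with vectors `U` and `H` of null statistics and their 5%
#'   quantiles `q5_U`, `q5_H`.
#' @export
permutation_null <- function(observed, locations, scheme = NULL, delta_loc = NULL,
                             model = c("two_class", "linearized"),
                             outflow = NULL, n_reps = 1000, seed = NULL,
                             drop_joint_zeros = FALSE) {
  model <- match.arg(model)
  if (n_reps < 20) warning("fewer than 20 permutation replicates: the 5% quantile is unreliable")
  locations <- validate_locations(locations)
  distances <- compute_distances(locations)
  ctx <- comparison_context(locations, distances)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(outflow)) { O <- observed; diag(O) <- 0; outflow <- rowSums(O) }
  off <- row(observed) != col(observed)
  pred_std <- round_half_away(ctx$P_std * outflow)
  err_std <- abs(pred_std - observed)
  base <- if (model == "two_class") locations$class else delta_loc
  if (is.null(base)) stop("supply class labels (two_class) or delta_loc (linearized)")
  U <- numeric(n_reps); H <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    perm <- sample(base)
    P <- modified_P_for(ctx, model, perm, scheme)
    err <- abs(round_half_away(P * outflow) - observed)
    mw <- mann_whitney_one_sided(err[off], err_std[off],
                                 drop_joint_zeros = drop_joint_zeros, exact = FALSE)
    U[r] <- mw$statistic
    H[r] <- sum(err > 0)
  }
  list(U = U, H = H,
       q5_U = stats::quantile(U, 0.05, names = FALSE),
       q5_H = stats::quantile(H, 0.05, names = FALSE))
}

#' Full model-comparison protocol
#'
#' Compares the modified radiation model (with the covariate-based class
#' assignment carried by `locations`/`delta_loc`) against the standard model
#' on an observed OD matrix: one-sided Mann-Whitney on the off-diagonal
#' absolute errors, Hamming distances with the binomial significance test,
#' and permutation nulls over random class reassignments. Each branch is
#' significant only when its statistical test rejects at level `alpha` AND
#' the observed statistic beats the 5% quantile of its permutation null; the
#' overall verdict requires both branches.
#'
#' @inheritParams permutation_null
#' @param alpha significance level (default 0.05).
#' @return Object of class `"mobility_comparison"`.
#' @export
compare_models <- function(observed, locations, scheme = NULL, delta_loc = NULL,
                           model = c("two_class", "linearized"),
                           outflow = NULL, n_reps = 1000, seed = NULL,
                           drop_joint_zeros = FALSE, alpha = 0.05) {
  model <- match.arg(model)
  locations <- validate_locations(locations)
  distances <- compute_distances(locations)
  ctx <- comparison_context(locations, distances)
  if (is.null(outflow)) { O <- observed; diag(O) <- 0; outflow <- rowSums(O) }
  off <- row(observed) != col(observed)
  L <- nrow(observed)

  pred_std <- round_half_away(ctx$P_std * outflow)
  assignment <- if (model == "two_class") locations$class else delta_loc
  if (is.null(assignment)) stop("supply class labels (two_class) or delta_loc (linearized)")
  P_mod <- modified_P_for(ctx, model, assignment, scheme)
  pred_mod <- round_half_away(P_mod * outflow)

  err_std <- abs(pred_std - observed)
  err_mod <- abs(pred_mod - observed)
  mw <- mann_whitney_one_sided(err_mod[off], err_std[off],
                               drop_joint_zeros = drop_joint_zeros, exact = FALSE)
  h_mod <- sum(err_mod > 0); h_std <- sum(err_std > 0)
  bt <- binomial_hamming_test(h_mod, h_std, L)
  null <- permutation_null(observed, locations, scheme = scheme,
                           delta_loc = delta_loc, model = model,
                           outflow = outflow, n_reps = n_reps, seed = seed,
                           drop_joint_zeros = drop_joint_zeros)
  mw_signif <- mw$p.value < alpha && mw$statistic < null$q5_U
  hm_signif <- bt$p.value < alpha && h_mod < null$q5_H
  structure(list(model = model, alpha = alpha,
                 mw = mw, hamming = list(mod = h_mod, std = h_std),
                 binomial = bt, null = null,
                 tally_mod = estimation_tally(pred_mod, observed),
                 tally_std = estimation_tally(pred_std, observed),
                 mw_significant = mw_signif, hamming_significant = hm_signif,
                 verdict = mw_signif && hm_signif),
            class = "mobility_comparison")
}

#' Calibration and power study of the comparison protocol
#'
#' Runs the full verdict procedure on synthetic systems with known ground
#' truth. In a `"calibration"` replicate the observed fluxes are multinomial
#' draws from the STANDARD model and the penalized class is assigned from a
#' covariate independent of the mobility structure, so the verdict should
#' fire at most at about the significance level. In a `"power"` replicate
#' the observed fluxes come from the two-class modified model and the
#' protocol uses the TRUE classes, so the verdict should fire in the
#' majority of replicates.
#'
#' @param type `"calibration"` or `"power"`.
#' @param n_replicates number of synthetic replicates.
#' @param L locations per system.
#' @param delta penalization used by the protocol (and, for power, by the
#'   generator).
#' @param pop_max largest Zipf population.
#' @param n_reps permutation replicates inside each verdict.
#' @param mobile_fraction outflow fraction of each population.
#' @param penalized_fraction fraction of penalized locations.
#' @param seed master seed; every replicate derives its own streams from it.
#' @return Logical vector of verdicts, one per replicate.
#' @export
protocol_study <- function(type = c("calibration", "power"), n_replicates = 200,
                           L = 25, delta = 1 + 1e-4, pop_max = 1e5,
                           n_reps = 200, mobile_fraction = 0.0785,
                           penalized_fraction = 0.15, seed = 1) {
  type <- match.arg(type)
  set.seed(seed)
  sub <- matrix(sample.int(2^31 - 2, 3 * n_replicates), ncol = 3)
  vapply(seq_len(n_replicates), function(r) {
    sys <- generate_system(L = L, pop_max = pop_max,
                           penalized_fraction = penalized_fraction,
                           seed = sub[r, 1])
    if (type == "calibration") {
      od <- generate_od(sys, "standard", mobile_fraction = mobile_fraction,
                        seed = sub[r, 2])
      set.seed(sub[r, 2] %% 1000 + r)
      sys$class <- assign_binary_top(stats::runif(L), penalized_fraction)
    } else {
      od <- generate_od(sys, "two_class", delta = delta,
                        mobile_fraction = mobile_fraction, seed = sub[r, 2])
    }
    cmp <- compare_models(od$observed, sys, scheme = c(1, delta),
                          model = "two_class", n_reps = n_reps,
                          seed = sub[r, 3])
    cmp$verdict
  }, logical(1))
}

#' @export
print.mobility_comparison <- function(x, ...) {
  cat("Modified vs standard radiation model (", x$model, " variant)\n", sep = "")
  cat(sprintf("  Mann-Whitney: U = %.1f, one-sided p = %.4g (null 5%% quantile %.1f) -> %s\n",
              x$mw$statistic, x$mw$p.value, x$null$q5_U,
              if (x$mw_significant) "significant" else "not significant"))
  cat(sprintf("  Hamming: modified %d vs standard %d, binomial p = %.4g (null 5%% quantile %.1f) -> %s\n",
              x$hamming$mod, x$hamming$std, x$binomial$p.value, x$null$q5_H,
              if (x$hamming_significant) "significant" else "not significant"))
  cat("  tallies (over/correct/under): modified",
      paste(x$tally_mod, collapse = "/"), "| standard",
      paste(x$tally_std, collapse = "/"), "\n")
  cat("  verdict:", if (x$verdict)
    "modified model outperforms the standard model" else
    "no significant improvement", "\n")
  invisible(x)
}
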