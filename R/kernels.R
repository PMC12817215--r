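#' Standard radiation probability
#'
#' Probability that a mover from an origin with population `m` stops at a
#' destination with population `n`, given a total intervening population `s`:
#' `m n / ((m + s)(m + n + s))`.
#'
#' @param m origin population (>= 1).
#' @param n destination population (>= 1).
#' @param s intervening population (>= 0).
#' @return Unnormalized stopping probability in (0, 1). Vectorized.
#' @export
radiation_probability <- function(m, n, s) {
  if (any(m < 1) || any(n < 1)) stop("populations must be >= 1")
  if (any(s < 0)) stop("intervening population must be >= 0")
  m * n / ((m + s) * (m + n + s))
}

# delta^(-x) in log space: safe for exponents up to population scale (1e6+)
pow_neg <- function(delta, x) exp(-x * log(delta))

#' Two-class modified radiation probability (closed forms)
#'
#' Closed-form stopping probabilities when locations split into a reference
#' class 1 (uniform benefit distribution on \[0, 1\]) and a penalized class 2
#' whose distribution is compressed to \[0, 1/delta\]. The four origin ->
#' destination cases are evaluated from the exact closed forms; all reduce to
#' [radiation_probability()] with `s = s1 + s2` at `delta = 1`.
#'
#' For `delta < 1` (class 2 advantaged) the same closed forms apply after the
#' scale-equivalence relabeling: compressing class 2 by `delta` is the same
#' system as compressing class 1 by `1/delta`, so class roles and the
#' per-class intervening populations are swapped internally.
#'
#' @param m origin population; @param n destination population.
#' @param s1,s2 intervening population of class 1 and class 2.
#' @param origin_class,dest_class 1 or 2.
#' @param delta class-2 scaling factor, > 0 (delta > 1 penalizes class 2).
#' @return Unnormalized probability. Vectorized over numeric arguments.
#' @export
modified_probability_two_class <- function(m, n, s1, s2, origin_class, dest_class, delta) {
  if (any(delta <= 0)) stop("delta must be > 0")
  if (any(m < 1) || any(n < 1)) stop("populations must be >= 1")
  if (any(s1 < 0) || any(s2 < 0)) stop("intervening populations must be >= 0")
  if (!all(origin_class %in% 1:2) || !all(dest_class %in% 1:2))
    stop("origin_class and dest_class must be 1 or 2")
  len <- max(length(m), length(n), length(s1), length(s2),
             length(origin_class), length(dest_class), length(delta))
  m <- rep_len(m, len); n <- rep_len(n, len)
  s1 <- rep_len(s1, len); s2 <- rep_len(s2, len)
  origin_class <- rep_len(origin_class, len)
  dest_class <- rep_len(dest_class, len)
  delta <- rep_len(delta, len)
  low <- delta < 1
  out <- numeric(len)
  if (any(low))  # relabel so the wider-support class is the reference
    out[low] <- mod2_core(m[low], n[low], s2[low], s1[low],
                          3L - origin_class[low], 3L - dest_class[low],
                          1 / delta[low])
  if (any(!low))
    out[!low] <- mod2_core(m[!low], n[!low], s1[!low], s2[!low],
                           origin_class[!low], dest_class[!low], delta[!low])
  out
}

# the printed two-class closed forms (reference class 1, delta >= 1)
mod2_core <- function(m, n, s1, s2, oc, dc, delta) {
  s <- s1 + s2
  pR <- radiation_probability(m, n, s)
  key <- paste0(oc, dc)
  p <- numeric(length(pR))
  for (k in c("22", "12", "21", "11")) {
    i <- key == k
    if (!any(i)) next
    p[i] <- switch(k,
      "22" = pR[i] * pow_neg(delta[i], s1[i]),
      "12" = pR[i] * pow_neg(delta[i], m[i] + s1[i]),
      "21" = pR[i] * pow_neg(delta[i], s1[i]) *
               (1 + (m[i] + s[i]) / n[i] * (1 - pow_neg(delta[i], n[i]))),
      "11" = pR[i] * (s2[i] * (m[i] + s[i]) *
                        pow_neg(delta[i], m[i] + n[i] + s1[i]) /
                        (n[i] * (m[i] + n[i] + s1[i])) +
                      (m[i] + s[i]) * (m[i] + n[i] + s[i]) /
                        ((m[i] + s1[i]) * (m[i] + n[i] + s1[i])) -
                      s2[i] * (m[i] + n[i] + s[i]) *
                        pow_neg(delta[i], m[i] + s1[i]) /
                        (n[i] * (m[i] + s1[i]))))
  }
  p
}

#' Linearized modified radiation probability (any number of classes)
#'
#' First-order expansion around delta = 1:
#' `p = pR * (1 + sum_c (delta_c - 1) * (m 1\{c_i=c\} - (m+s) 1\{c_j=c\} + s^(c)))`.
#' For two classes this reproduces the coefficients rho21 = m + s2,
#' rho22 = -s1, rho12 = -m - s1 and rho11 = s2. Negative values (possible for
#' large deltas) are clipped at zero with a warning.
#'
#' @param m,n origin and destination populations.
#' @param s_by_class numeric vector of intervening populations per class.
#' @param origin_class,dest_class class indices.
#' @param delta numeric vector of per-class scaling factors (class 1 must be 1).
#' @param warn_band warn when any |delta - 1| exceeds this band (the expansion
#'   is only meant for deltas near 1).
#' @return Unnormalized probability (scalar).
#' @export
linearized_probability <- function(m, n, s_by_class, origin_class, dest_class,
                                   delta, warn_band = 1e-2) {
  if (any(delta <= 0)) stop("delta must be > 0")
  if (length(delta) != length(s_by_class))
    stop("delta and s_by_class must have one entry per class")
  if (any(abs(delta - 1) > warn_band))
    warning("linearized model used with |delta - 1| > ", warn_band,
            "; the first-order expansion may be inaccurate")
  s <- sum(s_by_class)
  pR <- radiation_probability(m, n, s)
  rho <- m * (delta[origin_class] - 1) - (m + s) * (delta[dest_class] - 1) +
    sum((delta - 1) * s_by_class)
  p <- pR * (1 + rho)
  if (p < 0) {
    warning("linearized probability clipped at 0")
    p <- 0
  }
  p
}

#' General order-statistic stopping probability (integral engine)
#'
#' Evaluates the absorption--emission integral for an arbitrary number of
#' classes with rectangular benefit distributions: the integrand is the
#' density of the maximum of `m` origin-class draws, times the probability
#' that every intervening location of every class stays below the threshold,
#' times the probability that at least one of the `n` destination draws
#' exceeds it. For rectangular distributions the integrand is piecewise
#' monomial (breakpoints at 1/delta_k), so each piece is integrated exactly
#' in closed form, in log space; the result is exact to machine precision
#' even for populations of 1e6.
#'
#' @param m,n origin and destination populations.
#' @param s_by_class numeric vector of per-class intervening populations.
#' @param origin_class,dest_class class indices into `delta`.
#' @param delta per-class scaling factors (> 0).
#' @return Unnormalized stopping probability (scalar).
#' @export
general_probability_integral <- function(m, n, s_by_class, origin_class,
                                         dest_class, delta) {
  C <- length(delta)
  if (length(s_by_class) != C) stop("s_by_class and delta lengths differ")
  if (any(delta <= 0)) stop("delta must be > 0")
  if (m < 1 || n < 1) stop("populations must be >= 1")
  d_o <- delta[origin_class]
  d_d <- delta[dest_class]
  upper <- min(1 / d_o, 1 / d_d)  # beyond: origin density 0 or dest term 0
  brk <- sort(unique(c(0, 1 / delta[s_by_class > 0], upper)))
  brk <- c(brk[brk < upper], upper)
  total <- 0
  for (t in seq_len(length(brk) - 1L)) {
    a <- brk[t]; b <- brk[t + 1L]
    mid <- (a + b) / 2
    active <- delta * mid < 1          # classes whose CDF has not saturated
    p_exp <- (m - 1) + sum(s_by_class[active])
    logA <- log(m) + m * log(d_o) + sum(s_by_class[active] * log(delta[active]))
    piece_term <- function(q, extra_log) {
      # integral of z^(q-1) over [a, b], scaled by exp(logA + extra_log)
      lg <- q * log(b) + if (a > 0) log1p(-exp(q * (log(a) - log(b)))) else 0
      exp(logA + extra_log + lg - log(q))
    }
    t1 <- piece_term(p_exp + 1, 0)
    t2 <- piece_term(p_exp + n + 1, n * log(d_d))
    total <- total + max(t1 - t2, 0)
  }
  total
}
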