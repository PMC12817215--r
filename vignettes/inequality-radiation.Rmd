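---
title: "Inequality-aware radiation models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inequality-aware radiation models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ineqrad)
```

## The model

The radiation model predicts origin–destination fluxes from populations and
geometry alone. A mover leaving location $i$ (population $m_i$) draws a
benefit threshold — the maximum of $m_i$ draws from a benefit distribution
$p(z)$ — and settles at the closest location whose *opportunity* (the
maximum of $n_j$ draws for a destination of population $n_j$) exceeds that
threshold. Integrating out the threshold gives the classic closed form

$$p^R_{ij} = \frac{m_i\, n_j}{(m_i + s_{ij})(m_i + n_j + s_{ij})},$$

where $s_{ij}$ is the total population strictly within the circle of radius
$r_{ij}$ centred at $i$, excluding $i$ and $j$. Fluxes are
$T_{ij} = T_i\, p_{ij}$ after setting $p_{ii} = 0$ and row-normalizing, with
the outflow totals $T_i$ known or proportional to population.

The standard model is equity-blind: two equally sized locations offer
identical opportunities regardless of conflict, flooding, or poverty. The
inequality-aware family implemented here partitions locations into classes
$k = 1, \dots, C$ and compresses the benefit distribution of class $k$ by a
factor $\delta_k$:
$p^{(k)}(z) = \delta_k\, p(z\,\delta_k)$, with class 1 the reference
($\delta_1 = 1$) and $\delta_k > 1$ penalizing class $k$ — both lowering the
thresholds of movers who leave its locations and making its locations less
attractive as destinations. With the rectangular reference
$p(z) = \mathrm{Rect}_1(z)$, class $k$ is uniform on $[0, 1/\delta_k]$.

The stopping probability becomes an order-statistic integral: the density of
the origin's maximum, times the probability that no intervening location of
any class beats the threshold, times the probability that the destination
does. Three evaluation routes are provided, and they are required to agree:

* **`two_class`** — the exact closed forms for $C = 2$. Each case
  (origin/destination in the reference or penalized class) multiplies
  $p^R_{ij}$ by factors involving $\delta^{-s^{(1)}_{ij}}$,
  $\delta^{-m_i - s^{(1)}_{ij}}$, etc., where $s^{(k)}_{ij}$ is the class-$k$
  part of the intervening population.
* **`linearized`** — the first-order expansion around $\delta = 1$,
  $p_{ij} = p^R_{ij}\,[1 + \sum_c (\delta_c - 1)\,\rho^{(c)}_{ij}]$ with
  $\rho^{(c)}_{ij} = m_i \mathbf{1}\{c_i = c\} - (m_i + s_{ij})\mathbf{1}\{c_j = c\} + s^{(c)}_{ij}$.
  For two classes this reproduces the coefficients
  $\rho^{21} = m + s^{(2)}$, $\rho^{22} = -s^{(1)}$,
  $\rho^{12} = -m - s^{(1)}$, $\rho^{11} = s^{(2)}$. The general-$C$ form is
  the package's additive superposition of per-class first-order responses;
  it is validated numerically against the integral engine rather than taken
  from a printed multi-class formula, and it is exactly the derivative of
  the integral at $\delta = 1$ (each coefficient was re-derived analytically
  from the order-statistic integral).
* **`integral`** — the general engine for any $C$. For rectangular
  distributions the integrand is piecewise *monomial* with breakpoints at
  $1/\delta_k$, so every piece has a closed-form antiderivative. The engine
  integrates piece by piece in log space, which keeps it exact (to machine
  precision) even for populations of $10^6$, where adaptive quadrature would
  miss the boundary layer near the upper support limit. This is why the
  $\delta = 1$ equivalence can be asserted at $10^{-12}$ instead of a
  quadrature tolerance.

A fourth route, the Monte-Carlo micro-simulator, realizes the decision
process agent by agent using exact inverse-transform sampling of maxima
($z = \delta^{-1} U^{1/n}$, $O(1)$ per draw at any population). It is the
ground-truth oracle: empirical frequencies conditioned on moving must match
every analytic variant within binomial error.

### Validity ranges and numerical choices

* The printed two-class closed forms assume the reference class has the
  wider support. For $\delta < 1$ (an *advantaged* second class) the package
  applies the exact scale-equivalence relabeling — swap class roles and use
  $1/\delta$ — under which the closed forms again match the integral engine
  to $\sim 10^{-12}$ relative. Without the relabeling the raw expressions
  are invalid for $\delta < 1$, which is easy to miss because they remain
  finite.
* $\delta^{-x}$ is always computed as $\exp(-x \log \delta)$; exponents
  reach population scale ($10^6$).
* The flux probability surface is continuous and once differentiable in
  $\delta$ at $\delta = 1$ but *not* twice differentiable (the saturation
  order of the class CDFs flips there), so derivative checks in the tests
  use one-sided Richardson differences.
* Circle membership is strict ($r_{i\ell} < r_{ij}$): locations exactly at
  the destination's distance are excluded from $s_{ij}$. This makes ties
  deterministic and is applied identically in the analytic models and the
  simulator, where equidistant destinations form a *shell* whose members do
  not block each other; an agent choosing among several acceptable
  shell members picks uniformly. (Sequential visiting of tied destinations
  would bias the first-visited one and break the correspondence with the
  strict-circle analytic convention.)
* Negative linearized probabilities (possible for aggressive $\delta$) are
  clipped at zero before normalization; the count is reported and surfaced
  as a warning. The linearized variant also warns when any
  $|\delta_k - 1| > 10^{-2}$, the band within which the first-order
  expansion is meant to operate.
* Rows with no positive mass (or zero outflow) stay zero — no imputation.
* Fluxes are rounded to the nearest integer, ties half away from zero.
  Normalization happens first, then multiplication by $T_i$, then rounding.
* Distances: haversine on the mean Earth radius 6371.0088 km for lat/lon
  input, Euclidean for planar km input, chosen from the input schema.

## Class assignment from inequality covariates

Two schemes map covariates (casualties per capita, flood exposure, Gini
index, poverty ratio, rent/income ratio, unemployment rate) to classes:

* **Binary top-fraction** (`assign_binary_top`): the top
  $\lceil f L \rceil$ locations by covariate value form the penalized class,
  default $f = 0.15$ — read as a count-based cut, not a value threshold;
  ties at the cut resolve by stable location order with a warning. Multiple
  covariates combine as the union of their penalized sets. Typical $\delta$
  values for this scheme are $1 + 10^{n}$, $n = -6 \dots -4$: with
  county-scale populations the relevant exponents $s \log\delta$ are then
  $O(1)$, which is precisely the regime where penalization reshapes fluxes.
* **Linear $\delta$ ramp** (`assign_linear_ramp`): $\delta = 1$ up to the
  90th percentile of the covariate (linear-interpolation quantile, R type
  7), then growing linearly to $1 + \Delta$ at the maximum; every distinct
  $\delta$ is its own class, so the linearized variant (whose cost does not
  grow with $C$) is the natural companion. Typical $\Delta$:
  $10^{-8} \dots 10^{-6}$.

No fitting or optimization selects $\delta$ or the thresholds; they are
order-of-magnitude choices, and the comparison protocol below is what
decides whether a given choice carries real information.

## The comparison protocol

`compare_models()` asks whether the inequality-aware model reconstructs an
observed OD matrix better than the standard model, using distribution-free
statistics on the absolute error matrices (diagonal excluded — both models
force $T_{ii} = 0$, so diagonal cells carry no information):

1. **One-sided Mann–Whitney** on the error samples, alternative "modified
   errors stochastically smaller". Exact mid-$p$
   ($P(U < u) + \tfrac12 P(U = u)$, full enumeration) for joint sizes up to
   20; tie-corrected normal approximation *without* continuity correction —
   the matching large-sample convention — otherwise. Identical samples give
   $p = 1/2$ under this convention. For sparse commuting-style data the
   cells where both models have zero error can be dropped first
   (`drop_joint_zeros`).
2. **Hamming distances** (nonzero cells of each error matrix) with an exact
   binomial test: the modified distance is referred to
   $\mathrm{Binomial}(L^2, \hat{p})$ with $\hat{p}$ estimated from the
   standard model's distance; the $p$-value is the exact lower tail.
3. **Permutation nulls**: the modified model is re-run under random class
   assignments of the same sizes (1000 replicates for binary schemes, 200
   for ramp schemes by default); the observed $U$ and Hamming distance must
   fall below the 5% quantiles of their null distributions. This penalizes
   the extra parameters: a covariate carrying no information about mobility
   does no better than a random labeling.

A branch is significant only when its test rejects at $\alpha = 0.05$ *and*
beats its permutation null; the overall verdict requires both branches.
Calibration and power of the whole procedure are measured by
`protocol_study()`: under a null covariate (observed fluxes from the
standard model, classes from an independent uniform covariate) the verdict
fires at no more than the nominal rate; under a true two-class generator at
$\delta = 1 + 10^{-4}$ with county-scale populations it detects the modified
model's superiority in effectively every replicate.

## The synthetic generator

`generate_system()` stands in for field data: Zipf rank-size populations
(exponent 1, largest location $10^5$ by default — county-like scale, chosen
so that $\delta = 1 + 10^{-4}$ penalties act in the $s\log\delta = O(1)$
regime), uniform coordinates in a 500 km box, a penalized fraction of 0.15,
outflows $T_i = 0.0785\, m_i$ (the commuting calibration), and an observable
covariate equal to the true class indicator with optional flip-noise plus
$U(0, 0.5)$ jitter. OD ground truth comes from `generate_od()` either as
rounded expectations or as multinomial draws (row sums exactly $T_i$).

What the generator does *not* emulate: real settlement geography and spatial
correlation of covariates, survey under-reporting, return migration, and
temporal aggregation. Passing tests on synthetic systems therefore establish
internal correctness (the analytic family, its oracles, and the protocol's
operating characteristics), not that any particular covariate drives
real-world migration.

### Problem sizes used in the shipped studies

The test suite and `scripts/acceptance.R` run: 100 systems ($L \le 50$) for
the $\delta = 1$ equivalence; 20 two-class systems with $10^5$ agents each
for the three-way oracle agreement; calibration over 200 replicates at
$L = 25$ with 200-replicate permutation nulls; and power over 20 replicates
under the true generator. These sizes give stable operating-characteristic
estimates (binomial SE on the calibration rate $\approx 0.015$) at a few
minutes of runtime.

## A worked two-city example

The minimal system showing why inequality-awareness matters: city 1 with
$n_1 = 10^4$ inhabitants, conflict-free; city 2 with $n_2 = 10^6$,
penalized. Under the standard model the metropolis always attracts
($p^R_{12} = n_2/(n_1+n_2) \approx 0.99$). With penalization there is a
crossover $\delta^\ast$ beyond which flight from the metropolis dominates:

```{r two-city}
two_city_fixture(1e4, 1e6, delta = 1)[c("p12", "p21")]
dstar <- crossover_delta(1e4, 1e6)
dstar - 1
two_city_fixture(1e4, 1e6, delta = 1 + 2 * (dstar - 1))[c("p12", "p21")]
```

The crossover sits at $\delta^\ast - 1 \approx 7 \times 10^{-5}$: deviations
from equity of order $1/n_1$ suffice, which is why the empirically relevant
penalties are tiny numbers like $1 + 10^{-4}$.

## Known limitations

* Closed forms exist only for the rectangular benefit distribution; other
  distributions (e.g. Pareto-like) would need the integral engine
  generalized to their CDFs.
* The lexicographic closest-acceptable-destination rule is a first-order
  behavioral approximation; the model reconstructs statistical structure of
  flux matrices, not individual fluxes, and large absolute errors on the
  biggest fluxes are expected.
* The linearized variant is trustworthy only while
  $\max_k |\delta_k - 1| \cdot \max_{ij} s_{ij} \ll 1$; outside that band it
  can go negative (clipped, warned) and its first-order premise fails.
* The multi-class closed-form superposition is validated numerically, not
  taken from a printed general-$C$ derivation; the integral engine is the
  authority whenever they disagree (they have not, within $10^{-8}$).
* Centroid averaging of settlement coordinates is done on raw lat/lon and
  is inappropriate for regions straddling the antimeridian.
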