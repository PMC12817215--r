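# ineqrad — inequality-aware radiation models of human mobility

Population-level mobility models (commuting, migration) almost universally
assume equity: equally sized places offer equal opportunities. That premise
fails exactly where flux prediction matters most — war zones, flooded
regions, deeply unequal urban systems. `ineqrad` implements a radiation-type
model family in which locations belong to classes with differently
compressed benefit distributions, so that a conflict-stricken metropolis can
*lose* people to a smaller, safer neighbour — a regime the standard
radiation model cannot produce — together with the statistical protocol for
deciding, on observed origin–destination data, whether inequality covariates
actually carry information about mobility.

It is written for quantitative geographers, epidemiologists building
metapopulation mobility matrices, and anyone evaluating spatial-interaction
models against observed OD fluxes.

## The model

The standard radiation model sends a mover from location $i$ to the closest
location whose *opportunity* (max of $n_j$ draws from a benefit distribution)
exceeds their threshold (max of $m_i$ draws), giving

$$p^R_{ij} = \frac{m_i n_j}{(m_i + s_{ij})(m_i + n_j + s_{ij})},
\qquad T_{ij} = T_i\, p_{ij},$$

with $s_{ij}$ the population strictly inside the circle of radius $r_{ij}$
around $i$ (excluding $i$, $j$). `ineqrad` partitions locations into classes
$k$ whose benefit distributions are compressed by factors $\delta_k \ge 1$
($p^{(k)}(z) = \delta_k\,p(z\delta_k)$; class 1 is the reference,
$\delta_1 = 1$), penalizing disadvantaged places both as origins of
demanding movers and as attractive destinations. Four computation routes are
provided and cross-validated: exact two-class closed forms, a linearized
multi-class variant, an exact piecewise order-statistic integral engine for
any number of classes, and a Monte-Carlo agent simulator.

Model comparison against observed fluxes uses one-sided Mann–Whitney tests
and Hamming distances on absolute-error matrices, an exact binomial
significance test, and permutation nulls over random class reassignments
(which penalize the extra parameters): the modified model "wins" only when
it beats both the tests and the nulls at $\alpha = 0.05$.

## Worked example

A 30-location synthetic system with Zipf populations (largest $10^5$), 15%
of locations penalized at $\delta = 1 + 10^{-4}$, outflows
$T_i = 0.0785\,m_i$, observed fluxes drawn multinomially from the two-class
ground truth:

```r
library(ineqrad)
sys <- generate_system(L = 30, pop_max = 1e5, penalized_fraction = 0.15, seed = 42)
od  <- generate_od(sys, "two_class", delta = 1 + 1e-4,
                   mobile_fraction = 0.0785, seed = 43)

fit <- radiation(sys, scheme = c(1, 1 + 1e-4), model = "two_class")
fit
#> Radiation mobility model (two_class variant)
#>   locations: 30 | classes: 2 | metric: euclidean
#>   deltas: 1, 1.0001

compare_models(od$observed, sys, scheme = c(1, 1 + 1e-4),
               model = "two_class", n_reps = 200, seed = 7)
#> Modified vs standard radiation model (two_class variant)
#>   Mann-Whitney: U = 299820.5, one-sided p = 2.329e-15 (null 5% quantile 356325.0) -> significant
#>   Hamming: modified 437 vs standard 581, binomial p = 7.666e-23 (null 5% quantile 518.0) -> significant
#>   tallies (over/correct/under): modified 224/433/213 | standard 281/289/300
#>   verdict: modified model outperforms the standard model
```

Reading the output: the modified model's absolute errors are stochastically
smaller than the standard model's (Mann–Whitney $p \approx 10^{-15}$), its
error matrix has 437 nonzero cells against 581 (binomial $p \approx
10^{-23}$), it estimates 433 of the 870 off-diagonal fluxes exactly against
289, and both statistics also beat the 5% quantile of 200 random
class-reassignment nulls — so the covariate-based class assignment, not the
extra parameters, is doing the work.

The minimal system showing the qualitative change (city 1: $10^4$ people,
safe; city 2: $10^6$, penalized):

```r
two_city_fixture(1e4, 1e6, delta = 1)[c("p12", "p21")]
#> $p12  0.990099      # standard model: the metropolis always attracts
#> $p21  0.00990099
crossover_delta(1e4, 1e6) - 1
#> 6.832202e-05        # beyond delta* the net flow reverses
```

See `vignettes/inequality-radiation.Rmd` for the model derivation, the
numerical design (exact piecewise integration, log-space exponents, strict
circle membership, tie shells) and the protocol's calibration/power
characteristics.

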