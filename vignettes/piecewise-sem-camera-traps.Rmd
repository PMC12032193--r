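---
title: "Piecewise SEM for multi-species camera-trap counts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise SEM for multi-species camera-trap counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtrapSEM)
```

## The model

camtrapSEM implements piecewise structural equation modelling for
multi-species camera-trap count data. The scientific question it serves is
the relative importance of top-down regulation (predators suppressing prey
and mesopredators), bottom-up regulation (prey and habitat supporting
predators), and landscape characteristics in structuring a mammal
assemblage observed at camera stations.

A model is a directed acyclic graph over two kinds of vertices. Landscape
covariates (elevation, terrain ruggedness, proportion forest, road density)
are *exogenous*: nothing in the model explains them. Species occurrence
counts are *endogenous*: each species $y_v$ gets its own *structured
equation*, a Poisson log-link regression on its parents in the graph,

$$y_v \sim \mathrm{Poisson}\!\big(\exp(\beta_{0v} + \textstyle\sum_{u \in
\mathrm{pa}(v)} \beta_{uv}\, x_u)\big).$$

Unlike covariance-based SEM, estimation is *local*: equations are fit one
at a time, which is what makes non-Gaussian responses and modest sample
sizes workable. Global fit is then assessed through the graph's testable
implications rather than a joint likelihood.

### Tests of directed separation and Fisher's C

Every pair of non-adjacent vertices that the DAG claims independent (given
the union of both vertices' parents) yields an *independence claim*. The
claim is tested by regressing one member on the other plus the conditioning
set; the claim's p-value is the Wald p of the extra predictor. With $k$
claims in the basis set,

$$C = -2 \sum_{i=1}^{k} \ln p_i \;\sim\; \chi^2_{2k}$$

under the null that the graph is consistent with the data; a
*non-significant* p supports the model. A complementary likelihood-ratio
$\chi^2$ compares each equation against a saturated counterpart (defined
below). `sem_fit()` returns both, per-claim detail, and per-equation
Nagelkerke pseudo-R² and standardized coefficients.

### Basis-set construction

`basis_set()` enumerates one claim per unordered non-adjacent pair with at
least one endogenous member. Exogenous–exogenous pairs are excluded: the
model places no constraint on covariate covariances (covariates are only
screened for collinearity beforehand, `pearson_correlations()` warns at
|r| ≥ 0.25). Pairs carrying a *correlated error* — an acknowledged
association without a causal path — are excluded too; that is precisely
what a correlated error means here.

The regression response of a claim must be endogenous. When only one
member is endogenous, it is the response. When both are and one is an
ancestor of the other, the descendant responds. When both are endogenous
and causally unordered, the test is not direction-symmetric for Poisson
responses, so both directions are fitted and the smaller p kept — the
conservative choice, guarding against accepting a model because the easier
direction was tested. All orderings (pairs, topological ties) are
lexicographic so outputs are byte-stable.

### The saturated chi-square

The likelihood-ratio statistic needs a saturated reference. We pin it as
*topological-predecessor saturation*: the saturated counterpart of each
equation regresses its response on every exogenous vertex plus every
endogenous vertex earlier in the deterministic topological order.
`chi2_gof()` reports its own df arithmetic (difference in parameter
counts). Residual df per equation is $n - (\text{predictors} + 1)$; note
that published tables for the motivating study show residual dfs one to
three lower than this arithmetic at the same n, an unexplained bookkeeping
difference we surface rather than force.

## The optimization protocol

`optimize_sem()` implements the stepwise protocol: in each pass, (1) fit
all equations and test all claims; (2) walk significant claims (p < α,
default α = 0.05, ascending p, ties lexicographic): a claim matching the
model's *whitelist* of biologically plausible paths is tentatively added
and kept only if Fisher's C decreases; a significant species–species claim
outside the whitelist becomes a correlated error (an association credited
to unmodelled ecology); anything else is rejected; (3) prune hypothesized
paths that are simultaneously non-significant and fitted with a sign
contradicting expectation. Non-significant paths with the expected sign are
retained — a hypothesis is not discarded merely for weak evidence.
Removals never re-enter and additions are never pruned in the same run, so
the loop terminates. "Biological plausibility" is never auto-judged: the
whitelist in the model specification is the single source of candidate
paths.

### Merging optimized models

`combine_specs()` builds the combined model from the union of the retained
paths of the two optimized models. Here the protocol as published is
under-determined: because significant sign-mismatched paths are *retained*,
the top-down model can keep `lynx -> hare` while the bottom-up model keeps
`hare -> lynx`, and longer cycles (`fox -> hare`, `hare -> lynx`,
`lynx -> fox`) arise the same way; a strict union is then not a DAG. Our
design choice: given the data, while the union is cyclic, the on-cycle
species–species path with the weakest support (largest Wald p refit within
its source model) is dropped. Without data a cyclic union is an error.
This reproduces the qualitative published end state — the combined model
keeps the direction with stronger support.

## Standardized coefficients

Raw link-scale estimates are not comparable across paths (a species
predictor enters as raw counts, a covariate as a z-score). The default
`latent_linear` method rescales as
$\beta^{*} = \beta \cdot \mathrm{sd}(x) / \mathrm{sd}(\hat\eta)$, with the
fitted linear predictor's spread standing in for the response's latent
scale; no extra error-variance term is added because the log link has no
canonical latent error variance. An `observation_empirical` alternative
uses the spread of observed counts through the link (zeros floored at
0.5). Consequence stated openly: standardized estimates are
method-dependent and should be compared only within one method; the method
used is recorded in every fit. Published standardized estimates for the
motivating study are therefore approximated, not bit-reproduced.

## The packaged model fixtures

`spec_topdown()`, `spec_bottomup()`, `spec_combined()` and the two
optimized variants encode the motivating study's hypothesized and final
models. The original path diagrams are published as figures; these fixtures
are *reconstructions* from the written hypotheses and the combined-model
coefficient table, and they carry three caveats. First, which species
pairs received correlated errors was never published; `spec_combined()`
encodes sixteen species–species correlated errors chosen deterministically
(the retained claims are the pairs hypothesized in an a-priori model but
absent from the combined model, plus the apex-carnivore pair) so that its
basis set has 13 claims and Fisher's C df 26, matching the published model
comparison. Second, the optimized top-down/bottom-up fixtures keep all
twelve vertices — species the study dropped remain as isolated vertices —
so the two specs share a vertex set and can be merged; their df bookkeeping
consequently differs from the published values for those two models.
Third, hypothesized expected signs for paths that the study later removed
are taken from its written rationale.

## The synthetic-data generator

`generate_covariates()` draws stations with elevation ~ U(663, 1617) m,
TRI ~ U(84, 494), road density ~ U(0.21, 0.34) km/km², and proportion
forest from a Beta rescaled to [0.1, 1] with mean 0.77 (concentration 8) —
the published ranges and means of the survey; only ranges and means are
published, so the uniform/Beta shapes are a modelling choice that is
irrelevant to the machinery being exercised. Default size is 140 station
rows, 64 winter and 76 autumn, assigned deterministically.

`generate_counts()` simulates species in topological order from the truth
DAG: covariate parents enter as scaled values, species parents as raw
simulated counts — mirroring the fitting pipeline, which scales landscape
variables only (species predictors are left on the count scale, consistent
with the small raw species-on-species estimates alongside larger
standardized ones in the published coefficient table). No effort offset is
simulated or fitted: occurrences are summed per station with no
camera-days term. A linear predictor above 30 on the link scale aborts
with the station and species named, rather than silently producing
astronomical means.

Per-species intercepts are not published; `calibrate_intercepts()` finds
them by bisection (in topological order, against the mean of the
conditional Poisson mean over 10 000 evaluation stations, fixed seed
1701), targeting the published per-station detection means — 3599
detections over 140 rows shared as fox 27%, red deer 22%, wild boar 19%,
roe deer 11%, lynx 9%, wolf 7%, wildcat 3%, hare 2%. `default_truth()`
bundles the combined-model DAG, its published link-scale coefficients, and
these calibrated intercepts.

What the generator deliberately omits — and hence what passing tests do
*not* establish about real surveys: no spatial autocorrelation between
stations, no detection/effort process, no zero-inflation or
overdispersion, no seasonal effect on counts (season is a bookkeeping
column, not a model covariate, matching the pooled single-model design).
The generator matches the fitted model's assumptions by construction, so
simulation results validate the machinery, not the ecology.

## Numerical choices

- IRLS with deviance-based convergence, relative tolerance 1e-8, at most
  100 iterations; standard errors from the inverse Fisher information;
  two-sided Wald p-values. `fit_poisson()` agrees with `stats::glm` to
  well under 1e-6 when both are run to tight tolerance (they stop at
  slightly different points at their default criteria).
- P-values are floored at 1e-300 before any logarithm, keeping Fisher's C
  finite and orderings stable.
- Nagelkerke R² is clamped to [0, 1]; a null log-likelihood of zero (a
  degenerate all-zero response) is an explicit error, not a NaN.
- Linear predictors are clamped at ±30 inside IRLS iterations for
  stability; the converged fit is reported unclamped.
- Scaling uses the sample sd (n−1); scaling an already-scaled table is a
  no-op and the composition of scalings is stored, so raw covariates stay
  recoverable.

## Problem sizes used by the tests and the acceptance script

Simulation-based checks use deliberately small, fixed designs chosen to
make Monte Carlo error negligible relative to the property being checked:
global type-I calibration at n = 300 with 500 replicates (binomial sd
≈ 0.01 around 0.05); omitted-path power at effect 0.5 with 200 replicates;
optimizer recovery and stability at n = 1000 with 50 replicates each;
parameter recovery at n = 1000 with 200 replicates; the full three-model
workflow at the survey's own n = 140 for 20 replicates. The calibration
DAG (three covariates, three species in a chain) is constructed so every
claim has a unique endogenous response, making the claim p-values
approximately independent uniforms — the regime where Fisher's C is exactly
chi-square.

## Known limitations

- Plain Poisson only: no negative binomial, zero-inflation, or random
  effects; overdispersed real data will reject good causal structures.
- No latent or composite variables, no cyclic SEM.
- The d-separation basis set treats the claim p-values as independent;
  with shared data this is an approximation (checked by simulation to hold
  at the calibration design, not guaranteed universally).
- The deposited survey data of the motivating study are not packaged;
  `run_study()` accepts any station CSV in the documented layout, and the
  reproduction test runs when the deposited table is placed at
  `inst/extdata/romania_sem_stations.csv`.
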