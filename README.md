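# camtrapSEM

Piecewise structural equation modelling for multi-species camera-trap
count data.

Ecologists ask whether a mammal community is structured from the top down
(predators suppressing prey and mesopredators), from the bottom up (prey
and habitat supporting predators), or mostly by the landscape itself.
camtrapSEM answers this with *piecewise* SEM: species occurrence counts at
camera stations are modelled as a network of Poisson log-link regressions
arranged on a causal DAG — species are endogenous vertices, landscape
covariates (elevation, terrain ruggedness index, proportion forest, local
road density) exogenous — and the network's fit is judged by its testable
independence claims rather than a joint covariance likelihood.

For a DAG with basis set of k independence claims (one per eligible
non-adjacent vertex pair, tested by regressing one member on the other
plus both members' parents), the global statistic is Fisher's C:

    C = -2 * sum(ln p_i)  ~  chi-square with 2k df,

with a *non-significant* p indicating the causal structure is consistent
with the data. A likelihood-ratio chi-square against topologically
saturated equations, per-equation Nagelkerke pseudo-R², and standardized
coefficients complete the toolkit. A stepwise optimizer implements the
survey protocol: significant claims matching a whitelist of biologically
plausible paths are added when they lower C, unexplained species-species
associations become correlated errors, and non-significant sign-mismatched
hypotheses are pruned. A synthetic-data generator emulates a Carpathian
winter/autumn camera survey (140 stations, eight species from wolf and
lynx down to hare) so every stage is testable at desk scale.

## Worked example

```r
library(camtrapSEM)

truth  <- default_truth()                      # combined DAG + published
survey <- simulate_stations(140, truth, 42)    # coefficients, calibrated
detection_summary(survey)                      # intercepts
#> Detections: 3613 total
#>    species total percent
#>        fox   971    26.9
#>   red_deer   797    22.1
#>  wild_boar   658    18.2
#>   roe_deer   390    10.8
#>       lynx   381    10.5
#>       wolf   253     7.0
#>    wildcat   106     2.9
#>       hare    57     1.6
#> Season share: winter 44%, autumn 56%

fit <- sem_fit(spec_combined(), scale_covariates(survey))
fit
#> Piecewise SEM fit (n = 140 )
#>   Fisher's C = 27.853, df = 26, p = 0.366
#>   chi-square = 25.887, df = 29, p = 0.632
#>   claims tested: 13
```

The simulated survey reproduces the published detection profile (fox most
detected at ~27%, hare rarest at ~2%), and the generating DAG is accepted
by the d-separation tests (p = 0.37 >> 0.05) with 13 claims, hence
Fisher's C on 26 df. Running the full three-model workflow —
`run_study(survey)` optimizes the hypothesized top-down and bottom-up
models separately, merges the retained paths, and compares all three:

```r
run_study(survey)$comparison
#>       model        C          C_p C_df     chi2       chi2_p chi2_df poor_fit
#> 1  combined  41.8453 3.074913e-01   38  27.1081 3.505059e-01      25    FALSE
#> 2 bottom_up 248.9502 2.490816e-21   72 208.3513 1.247072e-24      40     TRUE
#> 3  top_down 542.3926 2.700096e-73   72 492.9601 2.231037e-79      40     TRUE
```

Both single-process models are firmly rejected while the combined model
fits: community structure needs top-down, bottom-up, *and* landscape
paths at once. The same workflow applies unchanged to a real station
table read with `read_station_table("stations.csv")`.

The `analysis/` directory walks the same pipeline as numbered scripts
(`01_simulate_survey.R` ... `05_parameter_recovery.R`), each a short
narrative driver writing its tables under `results/`.

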