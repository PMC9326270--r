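# destchoice

Tools for analysing **pedestrian destination choice** in virtual
experiments. In these experiments participants conduct a trip of up to
five of six labelled destinations (A–F) under a hypothetical time
budget: each choice costs `w_d·d + w_o·o + ε` hypothetical minutes
(distance `d`, occupancy `o`, Gaussian noise `ε`), destinations may not
be revisited, and some conditions give participants an ordered
*schedule* of destinations to follow.

The package implements the full analysis pipeline for such data:

* a **multinomial logit** destination-choice model with per-decision
  normalised predictors,

  `P_i = exp(U_i) / Σ_k exp(U_k)`,  `U_i = β_occ·n̂_i + β_dist·d̂_i (+ β_des·q̂_i)`,

  where the schedule desirability of the destination at position `p`
  of the remaining schedule is `q = exp(−p)`;
* **maximum-likelihood calibration** (`fit_mle()`) with AIC reporting
  and a zero-parameter random-model reference (`random_model_aic()`);
* **inference**: participant-level bootstrap percentile intervals
  (`bootstrap_ci()`), permutation tests on the sum of squared
  parameter differences between conditions (`permutation_test()`), and
  likelihood-ratio tests for the desirability term
  (`likelihood_ratio_test()`);
* **two participant-clustering procedures**: threshold clustering on
  normalised cumulative distance/occupancy with automatic bimodality
  detection, and hierarchical clustering of per-individual parameter
  estimates, both compared to the aggregate model by summed AIC;
* **schedule adherence** via the Levenshtein distance between planned
  and realised destination sequences;
* a **virtual-experiment simulator** (`simulate_cohort()`) that
  generates synthetic cohorts with known ground truth — including
  shared transition noise, budget truncation and schedule conditions —
  so every stage of the pipeline is testable without external data.

See the vignette `vignettes/destination-choice-methods.Rmd` for the
model, the design decisions and the validation strategy.

## Worked example

```r
library(destchoice)

env  <- example_environment("open")               # bundled synthetic layout
spec <- cohort_spec(200, env, components = model_params(-4, -0.5), seed = 7)
sim  <- simulate_cohort(spec)

fit <- fit_mle(sim$data)
fit
#> <mnl_fit> two_param multinomial logit (1000 decisions)
#>  beta_occ beta_dist
#>   -3.9090   -0.6099
#>   logLik = -878.864, k = 2, AIC = 1761.7 (Nelder-Mead, converged)

random_model_aic(sim$data, "shrinking")
#> [1] 2631.7

bootstrap_ci(sim$data, B = 100, seed = 3)
#> <bootstrap_ci> 100 replicates, 95% percentile intervals (unit: participant, seed 3)
#>           estimate  lower  upper
#> beta_occ    -3.909 -4.283 -3.589
#> beta_dist   -0.610 -0.930 -0.290
```

The cohort was simulated with true parameters `(−4, −0.5)`: the fitted
busyness weight `β_occ ≈ −3.91` and distance weight `β_dist ≈ −0.61`
recover them within the bootstrap intervals, and the fitted AIC (1762)
is far below the random-model reference (2632), i.e. the model explains
the choices much better than chance. `run_pipeline()` chains the same
steps — fits, hypothesis tests, clustering and adherence — over several
conditions at once.

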