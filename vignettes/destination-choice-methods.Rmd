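---
title: "Modelling pedestrian destination choice: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pedestrian destination choice: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(destchoice)
```

## The experimental setting

destchoice analyses data from virtual destination-choice experiments.
Participants face an environment with six labelled destinations (A–F)
and an origin, and conduct a trip of up to five destination choices
under a hypothetical time budget. At each decision they see the layout
(hence relative distances) and the current occupancy of each
destination (head-counts), and they may not revisit a destination.
Choosing destination $i$ at decision $j$ consumes hypothetical time

$$T_i(j) = w_d\, d_{i,j} + w_o\, o_{i,j} + \varepsilon,
\qquad \varepsilon \sim N(\mu, \sigma^2),$$

where $d_{i,j}$ is the integer distance (arbitrary units, $0$–$10$)
from the current position, $o_{i,j}$ the occupancy at decision $j$, and
$w_d, w_o > 0$ environment-specific weights. When the budget runs out
the trip ends; the choice that overruns the budget is still recorded,
because a participant commits to it before learning the time cost.
Environments are defined in plain YAML files (`read_environment()`);
the bundled `open`, `closed` and `photo` environments carry *invented*
distance and occupancy tables that mirror this structure (budgets of 60
and 15 hypothetical minutes, noise variances 2 and 0.75) without
reproducing any particular study's tables.

A deliberate quirk of such experiments is that the world is *not*
simulated dynamically: the noisy transition times are realized once, so
two participants making the same decision sequence experience exactly
the same times. `realize_noise()` reproduces this by caching one noise
draw per (decision, position, destination) triple; a per-participant
noise policy is available for general simulation studies.

## The choice model

Choices are modelled with a multinomial logit. The probability of
choosing alternative $i$ from the choice set $C$ at a decision is

$$P_i = \frac{e^{U_i}}{\sum_{k \in C} e^{U_k}},$$

with linear utility

$$U_i = \beta_{occ}\, \hat n_i + \beta_{dist}\, \hat d_i
      \;(+\; \beta_{des}\, \hat q_i).$$

The predictors are normalised **per decision** to $[0, 1]$ by dividing
by the maximum value observed over the alternatives at that decision,
so the coefficients measure relative effect strengths and are
comparable across decisions with different scales. If a predictor is
identically zero at a decision, the normalised values are left at zero
("no signal") rather than dividing by zero.

$\beta_{occ}$ and $\beta_{dist}$ may take either sign (attraction or
repulsion); $\beta_{des}$ is constrained non-negative, since a schedule
can only pull choices towards itself — a negative weight would mean
deliberately doing the opposite of one's own plan.

### Schedule desirability

A schedule $S$ is an ordered list of intended destinations. The
desirability of the destination at (1-based) position $p$ of the
remaining schedule is $q = e^{-p}$; destinations already visited are
removed from the schedule for all later decisions. Two variants govern
destinations *absent* from the schedule:

* `rule` (default): absent destinations get $q = 0$.
* `worked_example`: absent destinations are appended to the tail of
  the remaining schedule (in canonical label order) before positions
  are assigned, so with a 5-entry schedule over 6 destinations the
  desirabilities are $(e^{-1}, \ldots, e^{-6})$.

Both are implemented because the two conventions genuinely coexist in
the literature on schedule-driven desirability and they disagree
precisely when a schedule does not cover all destinations. They
coincide whenever it does. The desirability entering the utility is
normalised per decision like the other predictors; an option to divide
by the global maximum $e^{-1}$ instead is available through
`normalize_predictors()` applied manually.

## Calibration

`fit_mle()` maximises the dataset log-likelihood — the sum over
*decisions* (the unit of observation) of the chosen alternative's
log-probability — with `stats::optim`. The default is Nelder–Mead
(relative tolerance $10^{-8}$, at most 2000 iterations) from the
starting point $(0, 0[, 0.1])$; `method = "L-BFGS-B"` uses the analytic
gradient and native box constraints and is the default inside
resampling loops, where thousands of refits occur. The log-likelihood
is concave, so the two methods agree away from the bounds (a unit test
checks this).

Parameters are boxed to $[-20, 20]$ (and $\beta_{des} \ge 0$). The box
matters for *per-individual* fits: with at most five decisions,
perfect separation is common and the unconstrained MLE diverges; the
cap keeps every estimate finite while being far wider than any
plausible cohort-level estimate. Under Nelder–Mead the box is enforced
by clip-and-penalise; non-convergence is flagged on the result rather
than thrown.

`random_model_aic()` provides the zero-parameter reference: every
available alternative equally likely, $\mathrm{LL} = \sum_j \ln(1/m_j)$.
Under the `full` policy ($m_j = m$ always) this is the closed form
$2N\ln m + 2k_{random}$. The choice-set policy is configurable because
recorded datasets are ambiguous on whether reference models should use
the shrinking no-revisit sets or the full destination set; both are
reported by the pipeline. $k_{random}$ defaults to 0 but is
configurable for comparability with reports that charge the random
model a small parameter count.

## Inference

* **Bootstrap** (`bootstrap_ci()`): units are resampled with
  replacement to the original unit count and the model refitted;
  percentile intervals at level 0.95 by default. The default unit is
  the *participant* (whole trajectory), preserving within-participant
  dependence between that participant's decisions; decision-level
  resampling is available as a sensitivity check. Non-convergent
  replicates are redrawn, capped at $10B$ draws.
* **Permutation test** (`permutation_test()`): statistic
  $\sum_k (\hat\beta_k^A - \hat\beta_k^B)^2$; participants are randomly
  re-allocated between the two conditions keeping each group's
  participant count fixed, so the amount of data per condition is
  preserved. The p-value is the proportion of permuted statistics
  $\ge$ the observed one (ties count as exceeding, which is
  conservative), floored at $1/n_{perm}$ so it stays in $(0, 1]$. The
  pooled participant list is sorted internally, which makes the
  p-value exactly invariant to swapping the group labels when group
  sizes are equal.
* **Likelihood-ratio test** (`likelihood_ratio_test()`): $2\Delta LL$
  against $\chi^2_{\Delta k}$, used to assess whether the desirability
  term improves fit. Because $\beta_{des}$ sits on the boundary of its
  parameter space under the null, the $\chi^2_1$ reference is
  conservative (the asymptotic null is
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$); the mixture reference is
  available via `boundary_mixture = TRUE` and the conservative plain
  reference is the default.

Every resampling function takes an explicit integer seed, recorded in
its result object, and restores the caller's RNG state on exit.

## Participant clustering

Two procedures, deliberately different in spirit:

1. **Threshold clustering on summary statistics.**
   `normalized_cumulative()` computes each participant's mean chosen
   distance (or occupancy) per decision — the *raw* quantities, not the
   per-decision-normalised predictors, since the summaries are meant to
   live on the scale participants experienced.
   `estimate_bimodal_threshold()` histograms these values (20 equal
   bins by default), smooths the counts with a light $(1,2,1)/4$
   kernel, and searches for two modes: local maxima reaching at least
   20% of the tallest bin, separated by a valley dropping below 50% of
   the smaller mode. No rule for mode-finding is standard here; these
   prominence settings were calibrated once on simulated unimodal
   Gaussians versus clearly bimodal mixtures (two Gaussians separated
   by many standard deviations) so that unimodal samples of $n = 200$
   are declared unimodal essentially always while clear mixtures are
   always split near the valley midpoint. If no qualifying pair of
   modes exists, no threshold is returned and no clustering is
   attempted. The threshold is the midpoint of the two winning modes'
   bin centres.
2. **Hierarchical clustering of per-individual estimates.**
   `per_individual_fits()` calibrates the model separately per
   participant; `hierarchical_clusters()` then applies agglomerative
   clustering (complete linkage, Euclidean distance on the estimate
   vectors — the defaults of `stats::hclust`) and cuts the dendrogram
   at a height (e.g. 1.75) or into exactly `k` clusters.

`clustered_model_comparison()` fits the model per cluster and reports
the *summed* per-cluster AIC against the aggregate fit's AIC. All
clusters, including outlier singletons from a dendrogram cut,
contribute to the sum by default — excluding them would silently
discard data from the comparison. A one-cluster assignment reproduces
the aggregate AIC exactly, which the tests assert.

## Schedule adherence

`levenshtein()` implements the plain Levenshtein distance (unit-cost
substitutions, insertions, deletions; no transpositions) between label
sequences, in C++ for speed with a vectorised interface
(`levenshtein_many()`). Operating on label *sequences* rather than
strings lets multi-character destination labels compare as whole
symbols. Insertions/deletions matter because realised trips can be
shorter than schedules when the time budget binds.
`adherence_summary()` scores every scheduled participant's planned
versus realised sequence and reports the distances, their histogram
and mean.

## The synthetic-cohort generator

`simulate_cohort()` *is* the virtual experiment: sequential sampling
from the model's own choice probabilities, shrinking choice sets,
per-decision normalisation, schedule desirability updated by
removal-on-visit, shared-noise transition times, and budget-truncated
trips with the overrunning choice recorded. Ground truth (each
participant's mixture component and schedule) is returned in a sidecar
table for recovery studies. Schedules under the `"chosen"` policy are
uniform random permutations of five of the six destinations — no
behavioural model of schedule formation is assumed, because none is
established; the `"given"` policy assigns one fixed schedule to
everyone.

What the generator deliberately does *not* emulate: learning across
repeated attempts, demographic heterogeneity beyond the parameter
mixture, dynamic crowding (occupancy reacting to other participants),
and any model of how people truly form schedules. Passing recovery
tests therefore validates the *estimation machinery* under the model's
own assumptions — it cannot certify that real participants behave like
the model.

## Numerical choices and problem sizes

* Softmax and log-likelihood use max-utility shifts; probabilities are
  exact to floating point against direct $e^U/\sum e^U$ evaluation
  (tested at $10^{-12}$).
* Degenerate inputs: single-alternative decisions contribute zero
  log-likelihood; all-zero predictors normalise to zero; empty cohorts
  are valid outputs of the generator but invalid inputs to fitting.
* Validation test sizes were chosen to finish on one CPU in minutes
  while leaving comfortable statistical margins: parameter recovery
  uses 50 cohorts of 200 participants with a 500-replicate bootstrap
  (coverage checked against a [0.90, 0.99] band); null calibration of
  the permutation test uses 200 runs of 200 permutations on 60+60
  participants; study-scale settings ($B = 10{,}000$,
  $n_{perm} = 10{,}000$) remain the documented defaults of the
  user-facing functions.

## Known limitations

* The percentile bootstrap can slightly under-cover at small cohort
  sizes; the participant unit is the right default but only an
  approximation when trajectories are truncated very unevenly.
* The box constraint biases per-individual estimates of extreme
  participants towards $\pm 20$; cluster *centroids* are therefore not
  unbiased estimates of extreme subgroup parameters.
* With at most five decisions per participant, per-individual
  estimates carry large sampling noise (especially $\beta_{dist}$),
  which limits how well *unsupervised* clustering of the estimate
  vectors can recover even widely separated mixture components; the
  validation suite measures this recovery rate rather than assuming
  it.
* Threshold-mode detection depends on the bin count; 20 bins is a
  sensible default for cohorts of one to two hundred participants but
  should be revisited for much smaller or larger samples.
* With the `rule` desirability variant and a schedule covering all but
  one destination, the unscheduled destination is maximally penalised;
  the `worked_example` variant softens this. Which convention a given
  external dataset was analysed under must be established before
  comparing fitted $\beta_{des}$ magnitudes.
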