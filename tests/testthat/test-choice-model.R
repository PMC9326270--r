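test_that("desirability follows exp(-position) with removal on visit", {
  S <- c("A", "B", "C", "D", "E")
  dests <- LETTERS[1:6]
  # worked-example variant: unscheduled destinations appended to the tail
  expect_equal(desirability_vector(S, character(), dests, "worked_example"),
               setNames(exp(-(1:6)), dests))
  expect_equal(desirability_vector(S, "A", dests, "worked_example"),
               setNames(c(0, exp(-(1:5))), dests))
  # rule variant: unscheduled destinations get zero
  expect_equal(desirability_vector(S, character(), dests, "rule"),
               setNames(c(exp(-(1:5)), 0), dests))
  expect_equal(desirability_vector(S, "A", dests, "rule"),
               setNames(c(0, exp(-(1:4)), 0), dests))
  # no schedule, no desire
  expect_equal(desirability_vector(character(), c("A", "B"), dests, "rule"),
               setNames(numeric(6), dests))
  expect_error(desirability_vector(S, "Z", dests), "unknown")
})

test_that("rule and worked-example variants agree on full-coverage schedules", {
  dests <- LETTERS[1:6]
  set.seed(5)
  for (i in 1:20) {
    S <- sample(dests)          # schedule covering all destinations
    visited <- head(S, sample(0:4, 1))
    expect_equal(desirability_vector(S, visited, dests, "rule"),
                 desirability_vector(S, visited, dests, "worked_example"))
  }
})

test_that("predictors are normalised by the per-decision maximum", {
  expect_equal(normalize_predictors(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalize_predictors(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(normalize_predictors(7), 1)
  expect_error(normalize_predictors(c(-1, 2)), "non-negative")
  expect_error(normalize_predictors(numeric()), "alternative")
})

test_that("utility is the weighted sum of normalised predictors", {
  expect_equal(utility(model_params(0, 0), 0.7, 0.3), 0)
  expect_equal(utility(model_params(-1, -2), 1, 0.5), -2)
  expect_equal(utility(model_params(-3.95, -0.40), 0.5, 1), -2.375)
  expect_equal(utility(model_params(-1, -1, 2), 0.5, 0.5, 0.25), -0.5)
  expect_error(utility(model_params(-1, -1), 1, 1, q_hat = 0.5), "beta_des")
  expect_error(utility(model_params(-1, -1, 2), 1, 1), "missing")
})

test_that("choice probabilities are a softmax over the choice set", {
  # equal utilities: uniform
  p <- choice_probabilities(model_params(0, 0), 1:4, 4:1)
  expect_equal(unname(p), rep(0.25, 4))
  # utilities (ln 2, 0) -> (2/3, 1/3)
  p2 <- choice_probabilities(model_params(log(2), 0), c(1, 1), c(1, 0),
                             normalized = TRUE)
  expect_equal(unname(p2), c(2, 1) / 3)
  expect_equal(sum(p2), 1)
  # single alternative
  expect_equal(unname(choice_probabilities(model_params(-3, 1), 5, 2)), 1)
})

test_that("probabilities are invariant to a constant shift in utilities", {
  set.seed(8)
  for (i in 1:20) {
    m <- sample(2:6, 1)
    nh <- runif(m); dh <- runif(m)
    params <- model_params(rnorm(1, 0, 3), rnorm(1, 0, 3))
    p1 <- choice_probabilities(params, dh, nh, normalized = TRUE)
    u <- utility(params, nh, dh) + 7.3   # shifted utilities
    expect_equal(unname(p1), unname(exp(u - max(u)) / sum(exp(u - max(u)))),
                 tolerance = 1e-12)
  }
})

test_that("a more negative occupancy weight shifts mass off the busiest option", {
  occ <- c(9, 2, 4); dist <- c(3, 3, 3)
  p_weak <- choice_probabilities(model_params(-1, -0.5), dist, occ)
  p_strong <- choice_probabilities(model_params(-6, -0.5), dist, occ)
  expect_lt(p_strong[1], p_weak[1])
})

test_that("log-likelihood sums per-decision chosen log-probabilities", {
  # zero parameters, one six-way decision -> ln(1/6)
  d1 <- build_choice_data(list(list(alt = LETTERS[1:6], dist = 1:6,
                                    occ = 6:1, chosen = "C")))
  expect_equal(log_likelihood(model_params(0, 0), d1), log(1 / 6))
  # additivity over disjoint trajectories
  cohort <- quick_cohort(6, seed = 21)$data
  ids <- unique(cohort$participant_id)
  a <- cohort[cohort$participant_id %in% ids[1:3], ]
  b <- cohort[cohort$participant_id %in% ids[4:6], ]
  p <- model_params(-2.2, -0.7)
  expect_equal(log_likelihood(p, cohort),
               log_likelihood(p, a) + log_likelihood(p, b))
  expect_lte(log_likelihood(p, cohort), 0)
})

test_that("log-likelihood matches per-record oracle recomputation", {
  sim <- quick_cohort(10, beta = c(-3, -1), seed = 31)$data
  params <- model_params(-2.5, -0.8)
  ll_oracle <- 0
  for (pid in unique(sim$participant_id)) {
    traj <- sim[sim$participant_id == pid, ]
    for (j in unique(traj$decision_index)) {
      dec <- traj[traj$decision_index == j, ]
      pr <- oracle_probs(params, dec$distance, dec$occupancy)
      ll_oracle <- ll_oracle + log(pr[dec$chosen == 1])
    }
  }
  expect_equal(log_likelihood(params, sim), unname(ll_oracle),
               tolerance = 1e-12)
})

test_that("mismatched parameter arity is rejected", {
  sim <- quick_cohort(3, seed = 41)$data   # no schedules
  expect_error(log_likelihood(model_params(-1, -1, 0.5), sim),
               "desirability")
})
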