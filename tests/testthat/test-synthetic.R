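test_that("simulated cohorts are reproducible and respect the container", {
  spec <- cohort_spec(25, toy_environment(), seed = 601)
  s1 <- simulate_cohort(spec)
  s2 <- simulate_cohort(spec)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
  expect_s3_class(s1$data, "choice_data")
  # no revisits, at most 5 decisions each
  seqs <- chosen_sequences(s1$data)
  expect_true(all(vapply(seqs, function(s) !anyDuplicated(s), logical(1))))
  expect_true(all(lengths(seqs) <= 5))
  # empty cohort is fine
  s0 <- simulate_cohort(cohort_spec(0, toy_environment(), seed = 1))
  expect_equal(nrow(s0$data), 0)
})

test_that("zero utilities make the first choice uniform over destinations", {
  env <- toy_environment()
  spec <- cohort_spec(3000, env, components = model_params(0, 0), seed = 602)
  sim <- simulate_cohort(spec)$data
  first <- sim[sim$decision_index == 1 & sim$chosen == 1, "alternative"]
  tab <- table(factor(first, levels = LETTERS[1:6]))
  gof <- suppressWarnings(chisq.test(tab))
  expect_gt(gof$p.value, 0.01)
})

test_that("extreme distance aversion deterministically picks the nearest", {
  # predictors are normalised per decision, so the utility gap between
  # the nearest and second-nearest option is beta_dist * (d2 - d1)/dmax;
  # the weight must be extreme relative to that gap for argmax dominance
  env <- toy_environment()          # from O, B is strictly nearest (d = 1)
  spec <- cohort_spec(50, env, components = model_params(0, -100), seed = 603)
  sim <- simulate_cohort(spec)$data
  first <- sim[sim$decision_index == 1 & sim$chosen == 1, "alternative"]
  expect_true(all(first == "B"))
})

test_that("shared noise means identical sequences see identical times", {
  env <- toy_environment(noise_sigma = 2, time_budget = 28)
  env <- realize_noise(env, seed = 604)
  set.seed(605)
  # replay two participants forced along the same sequence
  costs <- function() {
    visited <- character(); position <- env$origin; total <- numeric()
    for (j in 1:3) {
      pick <- c("B", "A", "C")[j]
      eps <- env$noise_table[j, position, pick]
      total <- c(total, elapsed_time(env, position, pick, j, eps))
      visited <- c(visited, pick); position <- pick
    }
    total
  }
  expect_identical(costs(), costs())
})

test_that("the time budget truncates trips, recording the overrunning choice", {
  env <- toy_environment(w_d = 5, w_o = 5, time_budget = 30)
  spec <- cohort_spec(40, env, seed = 606)
  sim <- simulate_cohort(spec)
  expect_true(all(sim$truth$n_decisions <= 5))
  expect_true(any(sim$truth$n_decisions < 5))   # budget binds
  expect_true(any(!sim$truth$completed))
  expect_true(all(sim$truth$n_decisions >= 1))  # overrun choice recorded
  # dropping the overrunning choice removes those last decisions
  spec_drop <- cohort_spec(40, env, seed = 606, drop_overrun = TRUE)
  sim_drop <- simulate_cohort(spec_drop)
  expect_true(all(sim_drop$truth$n_decisions <= sim$truth$n_decisions))
})

test_that("mixture components are drawn with the stated weights", {
  spec <- cohort_spec(400, toy_environment(),
                      components = list(
                        list(params = model_params(-8, -0.5), weight = 0.25),
                        list(params = model_params(-1, -0.5), weight = 0.75)),
                      seed = 607)
  sim <- simulate_cohort(spec)
  frac <- mean(sim$truth$component == 2)
  expect_gt(frac, 0.65)
  expect_lt(frac, 0.85)
  expect_error(cohort_spec(10, toy_environment(),
                           components = list(
                             list(params = model_params(-1, -1), weight = 0.4),
                             list(params = model_params(-2, -1), weight = 0.4))),
               "sum to 1")
})

test_that("chosen-schedule cohorts draw unique five-destination schedules", {
  spec <- cohort_spec(30, toy_environment(), condition = "schedule_chosen",
                      components = model_params(-2, -0.5, 1.5),
                      schedule = "chosen", seed = 608)
  sim <- simulate_cohort(spec)
  scheds <- schedules_of(sim$data)
  expect_length(scheds, 30)
  expect_true(all(vapply(scheds, length, integer(1)) == 5))
  expect_true(all(vapply(scheds, anyDuplicated, integer(1)) == 0))
  expect_gt(length(unique(vapply(scheds, paste, character(1),
                                 collapse = ""))), 5)
})

test_that("parameter arity must match the schedule policy", {
  expect_error(cohort_spec(5, toy_environment(),
                           components = model_params(-1, -1),
                           schedule = c("A", "B")),
               "beta_des")
  expect_error(cohort_spec(5, toy_environment(),
                           components = model_params(-1, -1, 1)),
               "beta_des")
  expect_error(simulate_participant(toy_environment(), model_params(-1, -1),
                                    schedule = c("A", "B")),
               "beta_des")
})
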