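test_that("normalised cumulative quantities are per-decision means", {
  decisions <- list(
    list(alt = c("A", "B"), dist = c(2, 5), occ = c(3, 1), chosen = "A"),
    list(alt = c("B", "C"), dist = c(4, 6), occ = c(7, 2), chosen = "B"))
  data <- build_choice_data(decisions)
  expect_equal(unname(normalized_cumulative(data, "distance")), 3)   # (2+4)/2
  expect_equal(unname(normalized_cumulative(data, "occupancy")), 5)  # (3+7)/2
  one <- build_choice_data(list(list(alt = c("A", "B"), dist = c(1, 2),
                                     occ = c(7, 3), chosen = "A")))
  expect_equal(unname(normalized_cumulative(one, "occupancy")), 7)
  # equals an independent mean over any simulated trajectory
  sim <- quick_cohort(10, seed = 401)$data
  v <- normalized_cumulative(sim, "distance")
  ch <- sim[sim$chosen == 1, ]
  for (pid in names(v)[1:3]) {
    expect_equal(v[[pid]], mean(ch$distance[ch$participant_id == pid]))
  }
})

test_that("a clear two-mode mixture yields a midpoint threshold", {
  set.seed(402)
  hits <- 0
  for (i in 1:10) {
    vals <- c(rnorm(100, 2, 0.5), rnorm(100, 8, 0.5))
    thr <- estimate_bimodal_threshold(vals, bins = 20)
    if (!is.null(thr) && thr >= 4 && thr <= 6) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("unimodal samples are declared unimodal almost always", {
  set.seed(403)
  nones <- 0
  for (i in 1:50) {
    vals <- rnorm(200)
    if (is.null(estimate_bimodal_threshold(vals, bins = 20))) nones <- nones + 1
  }
  expect_gte(nones, 45)  # >= 90% none-rate
  # constant values occupy one bin: no threshold
  expect_null(estimate_bimodal_threshold(rep(3.3, 50)))
})

test_that("threshold clustering partitions participants deterministically", {
  v <- setNames(c(1, 2, 9, 10), paste0("P", 1:4))
  asg <- threshold_clusters(v, 5)
  expect_equal(sort(as.integer(table(asg$cluster))), c(2L, 2L))
  expect_equal(nrow(asg), 4)
  expect_setequal(asg$participant_id, names(v))
  expect_warning(threshold_clusters(setNames(1:3, paste0("P", 1:3)), 99),
                 "empty")
})

test_that("per-individual fits stay within bounds even on tiny data", {
  sim <- quick_cohort(20, beta = c(0, 0), seed = 405)$data
  est <- per_individual_fits(sim, bound = 20)
  expect_equal(nrow(est), 20)
  expect_true(all(is.finite(est)))
  expect_true(all(abs(est) <= 20 + 1e-8))
  # a single-decision participant still fits without error
  one <- build_choice_data(list(list(alt = c("A", "B", "C"),
                                     dist = c(1, 4, 2), occ = c(5, 2, 3),
                                     chosen = "B")))
  e1 <- per_individual_fits(one)
  expect_equal(nrow(e1), 1)
  expect_true(all(is.finite(e1)))
})

test_that("hierarchical clustering separates constructed estimate clouds", {
  # two points distance 1 apart, cut at 2 -> one cluster
  est <- rbind(P1 = c(0, 0), P2 = c(1, 0))
  colnames(est) <- c("beta_occ", "beta_dist")
  asg <- hierarchical_clusters(est, cut_height = 2)
  expect_equal(length(unique(asg$cluster)), 1)
  # two tight clouds 10 apart, cut between -> exactly the clouds
  set.seed(406)
  cloud <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
                 matrix(rnorm(40, 10, 0.2), ncol = 2))
  rownames(cloud) <- sprintf("P%02d", 1:40)
  colnames(cloud) <- c("beta_occ", "beta_dist")
  asg2 <- hierarchical_clusters(cloud, cut_height = 5)
  expect_equal(length(unique(asg2$cluster)), 2)
  expect_equal(length(unique(asg2$cluster[1:20])), 1)
  expect_equal(length(unique(asg2$cluster[21:40])), 1)
  expect_false(asg2$cluster[1] == asg2$cluster[21])
})

test_that("hierarchical clustering is invariant to participant order", {
  set.seed(407)
  est <- matrix(rnorm(60), ncol = 2,
                dimnames = list(sprintf("P%02d", 1:30),
                                c("beta_occ", "beta_dist")))
  a1 <- hierarchical_clusters(est, k = 3)
  perm <- sample(30)
  a2 <- hierarchical_clusters(est[perm, ], k = 3)
  m1 <- setNames(a1$cluster, a1$participant_id)
  m2 <- setNames(a2$cluster, a2$participant_id)
  # same partition up to label renaming
  tab <- table(m1[names(m2)], m2)
  expect_equal(sum(tab > 0), 3)
})

test_that("the one-cluster comparison reproduces the aggregate AIC", {
  sim <- quick_cohort(30, seed = 408)$data
  asg <- structure(data.frame(participant_id = unique(sim$participant_id),
                              cluster = "all", stringsAsFactors = FALSE),
                   class = c("cluster_assignment", "data.frame"),
                   method = "threshold")
  cmp <- clustered_model_comparison(sim, asg)
  expect_equal(cmp$clustered_aic, cmp$aggregate_aic)
})

test_that("true-label clustering beats the aggregate on a mixed cohort", {
  env <- toy_environment()
  spec <- cohort_spec(80, env,
                      components = list(
                        list(params = model_params(-8, -0.5), weight = 0.5),
                        list(params = model_params(-1, -0.5), weight = 0.5)),
                      seed = 409)
  sim <- simulate_cohort(spec)
  asg <- structure(data.frame(participant_id = sim$truth$participant_id,
                              cluster = as.character(sim$truth$component),
                              stringsAsFactors = FALSE),
                   class = c("cluster_assignment", "data.frame"),
                   method = "threshold")
  cmp <- clustered_model_comparison(sim$data, asg)
  expect_lt(cmp$clustered_aic, cmp$aggregate_aic)
})

test_that("random splitting of a homogeneous cohort costs about the penalty", {
  sim <- quick_cohort(100, seed = 410)$data
  pids <- unique(sim$participant_id)
  set.seed(411)
  half <- sample(pids, 50)
  asg <- structure(data.frame(participant_id = pids,
                              cluster = ifelse(pids %in% half, "a", "b"),
                              stringsAsFactors = FALSE),
                   class = c("cluster_assignment", "data.frame"),
                   method = "threshold")
  cmp <- clustered_model_comparison(sim, asg)
  k <- cmp$aggregate_fit$k
  expect_lt(abs(cmp$clustered_aic - (cmp$aggregate_aic + 2 * k)), 8)
})
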