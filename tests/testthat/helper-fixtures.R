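# Small in-code fixtures shared across the suite.

# a tiny deterministic environment with unit weights and no noise
toy_environment <- function(w_d = 1, w_o = 1, noise_sigma = 0,
                            time_budget = 1000) {
  dm <- rbind(O = c(3, 1, 5, 6, 8, 9),
              A = c(0, 2, 4, 5, 7, 9),
              B = c(2, 0, 3, 4, 6, 8),
              C = c(4, 3, 0, 2, 4, 6),
              D = c(5, 4, 2, 0, 3, 5),
              E = c(7, 6, 4, 3, 0, 3),
              F = c(9, 8, 6, 5, 3, 0))
  colnames(dm) <- LETTERS[1:6]
  om <- matrix(c(4, 1, 6, 2, 8, 3,
                 2, 5, 1, 7, 3, 6,
                 7, 2, 4, 1, 5, 2,
                 1, 6, 3, 5, 2, 7,
                 5, 3, 7, 2, 6, 1), nrow = 5, byrow = TRUE,
               dimnames = list(NULL, LETTERS[1:6]))
  environment_spec("toy", LETTERS[1:6], "O", dm, om,
                   w_d = w_d, w_o = w_o, noise_mu = 0,
                   noise_sigma = noise_sigma, time_budget = time_budget)
}

# simulate a base-condition cohort with given true parameters
quick_cohort <- function(n, beta = c(-4, -0.5), seed = 1,
                         env = toy_environment(), ...) {
  simulate_cohort(cohort_spec(n, env,
                              components = model_params(beta[1], beta[2]),
                              seed = seed, ...))
}

# hand-build a choice_data table from per-decision alternative lists
build_choice_data <- function(decisions, id = "P1", condition = "base",
                              schedule = NA_character_) {
  rows <- do.call(rbind, lapply(seq_along(decisions), function(j) {
    d <- decisions[[j]]
    data.frame(participant_id = id, condition = condition,
               decision_index = j, alternative = d$alt,
               distance = d$dist, occupancy = d$occ,
               desirability = if (is.null(d$des)) NA_real_ else d$des,
               chosen = as.integer(d$alt == d$chosen),
               schedule = schedule, stringsAsFactors = FALSE)
  }))
  as_choice_data(rows)
}

# independent per-decision softmax oracle on raw predictor values
oracle_probs <- function(params, dist, occ, des = NULL) {
  nd <- if (max(dist) > 0) dist / max(dist) else dist * 0
  no <- if (max(occ) > 0) occ / max(occ) else occ * 0
  u <- params[["beta_occ"]] * no + params[["beta_dist"]] * nd
  if (!is.null(des)) {
    nq <- if (max(des) > 0) des / max(des) else des * 0
    u <- u + params[["beta_des"]] * nq
  }
  exp(u) / sum(exp(u))
}

# exhaustive-search edit distance: recursively tries every first
# operation (delete, insert, substitute/match), independent of the
# dynamic-programming implementation under test
brute_force_edit <- function(a, b) {
  if (length(a) == 0L) return(length(b))
  if (length(b) == 0L) return(length(a))
  same <- if (a[1L] == b[1L]) 0L else 1L
  min(brute_force_edit(a[-1L], b[-1L]) + same,
      brute_force_edit(a[-1L], b) + 1L,
      brute_force_edit(a, b[-1L]) + 1L)
}

# all label sequences over `alphabet` with length <= max_len
all_sequences <- function(alphabet, max_len) {
  out <- list(character())
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len),
                      list(stringsAsFactors = FALSE)))
    out <- c(out, lapply(seq_len(nrow(grid)),
                         function(i) as.character(unlist(grid[i, ]))))
  }
  out
}
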