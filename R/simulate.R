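#' Specify a synthetic cohort
#'
#' Bundles everything [simulate_cohort()] needs to play out the virtual
#' experiment for `n` participants: the environment, the experimental
#' condition label, the true parameter mixture, the schedule policy,
#' the noise realisation policy and the choice-set policy.
#'
#' @param n Number of participants (may be 0).
#' @param env A [environment_spec()] object.
#' @param condition Condition label recorded in the output (e.g.
#'   `"base"`, `"schedule_chosen"`, `"schedule_given"`, `"closed"`,
#'   `"photo"`).
#' @param components List of mixture components, each a list with
#'   `params` (a [model_params()] vector) and `weight`; weights must be
#'   positive and sum to 1. A plain parameter vector is accepted as a
#'   single component.
#' @param schedule Schedule policy: `NULL` (none), a character vector
#'   of labels (every participant receives this schedule, e.g.
#'   `c("D","E","B","A","C")` — the given-schedule condition), or
#'   `"chosen"` (each participant draws a random permutation of 5 of
#'   the destinations, emulating free schedule creation, for which no
#'   behavioural model is assumed).
#' @param noise `"shared"` (default): transition noise is realized once
#'   per environment so identical decision sequences see identical
#'   times, as in the original experiment; or `"per_participant"` for
#'   fresh draws.
#' @param policy Choice-set policy, `"shrinking"` (default) or
#'   `"full"`.
#' @param desirability_variant Passed to [desirability_vector()].
#' @param drop_overrun If `TRUE`, the choice that overruns the time
#'   budget is discarded instead of recorded (default `FALSE`:
#'   participants commit to a choice before learning they ran out of
#'   time).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, env, condition = "base",
                        components = model_params(-4, -0.5),
                        schedule = NULL, noise = c("shared", "per_participant"),
                        policy = c("shrinking", "full"),
                        desirability_variant = c("rule", "worked_example"),
                        drop_overrun = FALSE, seed = 1L) {
  stopifnot(inherits(env, "dc_environment"), n >= 0)
  noise <- match.arg(noise)
  policy <- match.arg(policy)
  desirability_variant <- match.arg(desirability_variant)
  if (is.numeric(components)) {
    components <- list(list(params = components, weight = 1))
  }
  w <- vapply(components, function(c) c$weight, numeric(1L))
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-8) {
    stop("mixture weights must be positive and sum to 1", call. = FALSE)
  }
  has_schedule <- !is.null(schedule)
  for (c in components) {
    if (has_schedule != ("beta_des" %in% names(c$params))) {
      stop("components must carry beta_des exactly when a schedule policy ",
           "is set", call. = FALSE)
    }
  }
  if (has_schedule && !identical(schedule, "chosen")) {
    schedule <- as.character(schedule)
    if (anyDuplicated(schedule) ||
        !all(schedule %in% env$destinations)) {
      stop("given schedule must be unique known destinations", call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), env = env, condition = condition,
                 components = components, schedule = schedule,
                 noise = noise, policy = policy,
                 desirability_variant = desirability_variant,
                 drop_overrun = drop_overrun, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate one participant's trip
#'
#' Plays the sequential choice task: at each decision the available
#' alternatives (no revisits under the shrinking policy) are scored by
#' the multinomial-logit model on per-decision normalised occupancy,
#' distance and (if a schedule is present) desirability; a destination
#' is sampled; the elapsed hypothetical time `w_d d + w_o o + eps` is
#' subtracted from the remaining budget. The trip ends after five
#' choices or when the budget is exhausted — the overrunning choice is
#' recorded before the trip ends (participants commit to a choice
#' before learning they ran out of time), unless `drop_overrun`.
#'
#' Randomness is taken from the current RNG stream; seed the session or
#' use [simulate_cohort()] for reproducible cohorts.
#'
#' @param env A [environment_spec()] object; if it carries a realized
#'   noise table (see [realize_noise()]) transition noise is read from
#'   it, otherwise drawn fresh.
#' @param params A [model_params()] vector; must carry `beta_des`
#'   exactly when `schedule` is given.
#' @param schedule Character vector of scheduled destinations, or
#'   `NULL`.
#' @param id Participant identifier.
#' @param condition Condition label for the output rows.
#' @param policy,desirability_variant,drop_overrun See [cohort_spec()].
#' @return A list with `rows` (long-format data frame), `sequence`
#'   (chosen labels in order) and `completed` (finished five choices
#'   within budget).
#' @export
simulate_participant <- function(env, params, schedule = NULL,
                                 id = "P1", condition = "base",
                                 policy = c("shrinking", "full"),
                                 desirability_variant = c("rule",
                                                          "worked_example"),
                                 drop_overrun = FALSE) {
  policy <- match.arg(policy)
  desirability_variant <- match.arg(desirability_variant)
  has_schedule <- !is.null(schedule) && length(schedule) > 0L
  if (has_schedule != ("beta_des" %in% names(params))) {
    stop("params must carry beta_des exactly when a schedule is given",
         call. = FALSE)
  }
  n_dec_max <- min(5L, nrow(env$occupancy_table))
  remaining <- env$time_budget
  position <- env$origin
  visited <- character()
  sched_str <- if (has_schedule) format_schedule(schedule) else NA_character_
  rows <- vector("list", n_dec_max)
  completed <- FALSE
  for (j in seq_len(n_dec_max)) {
    alts <- available_alternatives(env, visited, policy)
    if (policy == "full") alts <- setdiff(alts, position)
    if (length(alts) == 0L) break
    d <- env$distance_table[position, alts]
    o <- env$occupancy_table[j, alts]
    q <- if (has_schedule) {
      desirability_vector(schedule, visited, env$destinations,
                          desirability_variant)[alts]
    } else NULL
    pr <- choice_probabilities(params, d, o, q, labels = alts)
    pick <- alts[sample.int(length(alts), 1L, prob = pr)]
    eps <- if (!is.null(env$noise_table)) {
      env$noise_table[j, position, pick]
    } else {
      rnorm(1L, env$noise_mu, env$noise_sigma)
    }
    spent <- elapsed_time(env, position, pick, j, eps)
    remaining <- remaining - spent
    overrun <- remaining <= 0
    if (!(overrun && drop_overrun)) {
      rows[[j]] <- data.frame(
        participant_id = id, condition = condition, decision_index = j,
        alternative = alts, distance = as.numeric(d),
        occupancy = as.numeric(o),
        desirability = if (has_schedule) as.numeric(q) else NA_real_,
        chosen = as.integer(alts == pick), schedule = sched_str,
        stringsAsFactors = FALSE)
      visited <- c(visited, pick)
    }
    position <- pick
    if (overrun) break
    if (j == n_dec_max) completed <- TRUE
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  list(rows = if (length(rows)) do.call(rbind, rows) else NULL,
       sequence = visited, completed = completed)
}

#' Simulate a synthetic cohort
#'
#' Generates `n` participant trajectories from a [cohort_spec()]: each
#' participant's true parameters are drawn from the mixture, a schedule
#' is assigned per the schedule policy, and the trip is played out with
#' [simulate_participant()]. Fully reproducible from the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort_sim` with `data` (a
#'   [as_choice_data()] table) and `truth` (a per-participant sidecar
#'   data frame: true mixture component, schedule, completion flag and
#'   decision count) for recovery studies.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  env <- spec$env
  if (spec$noise == "shared" && is.null(env$noise_table)) {
    env <- realize_noise(env, seed = spec$seed + 1L)
    set.seed(spec$seed)  # participant stream independent of the noise draw
  }
  n <- spec$n
  w <- vapply(spec$components, function(c) c$weight, numeric(1L))
  all_rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("P%04d", i)
    comp <- if (length(w) == 1L) 1L else sample.int(length(w), 1L, prob = w)
    params <- spec$components[[comp]]$params
    schedule <- if (is.null(spec$schedule)) {
      NULL
    } else if (identical(spec$schedule, "chosen")) {
      sample(env$destinations, min(5L, length(env$destinations)))
    } else {
      spec$schedule
    }
    tr <- simulate_participant(env, params, schedule, id = id,
                               condition = spec$condition,
                               policy = spec$policy,
                               desirability_variant =
                                 spec$desirability_variant,
                               drop_overrun = spec$drop_overrun)
    all_rows[[i]] <- tr$rows
    truth[[i]] <- data.frame(
      participant_id = id, component = comp,
      schedule = if (is.null(schedule)) NA_character_
                 else format_schedule(schedule),
      completed = tr$completed, n_decisions = length(tr$sequence),
      stringsAsFactors = FALSE)
  }
  all_rows <- all_rows[!vapply(all_rows, is.null, logical(1L))]
  df <- if (length(all_rows)) do.call(rbind, all_rows) else {
    data.frame(participant_id = character(), condition = character(),
               decision_index = integer(), alternative = character(),
               distance = numeric(), occupancy = numeric(),
               desirability = numeric(), chosen = integer(),
               schedule = character(), stringsAsFactors = FALSE)
  }
  structure(list(data = as_choice_data(df, policy = spec$policy),
                 truth = if (n) do.call(rbind, truth) else NULL,
                 spec = spec),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim> condition ", x$spec$condition, ", n = ", x$spec$n,
      ", seed ", x$spec$seed, "\n", sep = "")
  print(x$data)
  invisible(x)
}
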