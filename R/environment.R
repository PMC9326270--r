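#' Define a virtual experiment environment
#'
#' An environment holds everything needed to play out the virtual
#' destination-choice task: the destination labels, the origin, the
#' integer distance table between every position and every destination,
#' the per-decision occupancy table, the hypothetical-time cost weights,
#' the Gaussian noise parameters and the total time budget.
#'
#' The hypothetical time elapsed by choosing destination `i` at decision
#' `j` is `w_d * d + w_o * o + eps`, where `d` is the distance from the
#' current position, `o` the occupancy of `i` at decision `j`, and
#' `eps ~ N(noise_mu, noise_sigma^2)`. Distances are integers in
#' `[0, 10]` (arbitrary units); occupancies are positive integers.
#'
#' @param name Label for the environment (e.g. `"open"`).
#' @param destinations Character vector of destination labels
#'   (default `LETTERS[1:6]`).
#' @param origin Label of the initial position (must not be a
#'   destination label).
#' @param distance_table Integer matrix with one row per position
#'   (origin first, then destinations; rownames required) and one column
#'   per destination. Entries in `[0, 10]`.
#' @param occupancy_table Positive integer matrix with one row per
#'   decision index (1 to the trip length) and one column per
#'   destination.
#' @param w_d,w_o Positive cost weights: hypothetical minutes per
#'   distance unit and per person, respectively.
#' @param noise_mu,noise_sigma Mean and standard deviation (minutes) of
#'   the Gaussian noise added to each transition's elapsed time.
#' @param time_budget Total hypothetical minutes available for the trip.
#'
#' @return An object of class `dc_environment`.
#' @seealso [elapsed_time()], [available_alternatives()],
#'   [realize_noise()], [read_environment()]
#' @export
#' @examples
#' env <- example_environment("open")
#' elapsed_time(env, "O", "A", 1, noise_value = 0)
environment_spec <- function(name, destinations = LETTERS[1:6], origin = "O",
                             distance_table, occupancy_table,
                             w_d, w_o, noise_mu = 0, noise_sigma = 0,
                             time_budget = 60) {
  destinations <- as.character(destinations)
  origin <- as.character(origin)
  distance_table <- as.matrix(distance_table)
  occupancy_table <- as.matrix(occupancy_table)
  storage.mode(distance_table) <- "integer"
  storage.mode(occupancy_table) <- "integer"
  if (is.null(rownames(distance_table))) {
    rownames(distance_table) <- c(origin, destinations)
  }
  if (is.null(colnames(distance_table))) {
    colnames(distance_table) <- destinations
  }
  if (is.null(colnames(occupancy_table))) {
    colnames(occupancy_table) <- destinations
  }
  rownames(occupancy_table) <- NULL
  env <- structure(
    list(name = as.character(name), destinations = destinations,
         origin = origin, distance_table = distance_table,
         occupancy_table = occupancy_table,
         w_d = as.numeric(w_d), w_o = as.numeric(w_o),
         noise_mu = as.numeric(noise_mu),
         noise_sigma = as.numeric(noise_sigma),
         time_budget = as.numeric(time_budget),
         noise_table = NULL),
    class = "dc_environment")
  validate_environment(env)
  env
}

validate_environment <- function(env) {
  d <- env$destinations
  if (anyDuplicated(d)) stop("duplicate destination labels", call. = FALSE)
  if (env$origin %in% d) stop("origin must not be a destination", call. = FALSE)
  dt <- env$distance_table
  positions <- c(env$origin, d)
  missing_pos <- setdiff(positions, rownames(dt))
  if (length(missing_pos)) {
    stop("distance_table lacks rows for position(s): ",
         paste(missing_pos, collapse = ", "), call. = FALSE)
  }
  missing_dest <- setdiff(d, colnames(dt))
  if (length(missing_dest)) {
    stop("distance_table lacks columns for destination(s): ",
         paste(missing_dest, collapse = ", "), call. = FALSE)
  }
  if (anyNA(dt) || any(dt < 0L) || any(dt > 10L)) {
    stop("distances must be integers in [0, 10]", call. = FALSE)
  }
  ot <- env$occupancy_table
  if (!all(d %in% colnames(ot))) {
    stop("occupancy_table lacks columns for some destinations", call. = FALSE)
  }
  if (anyNA(ot) || any(ot <= 0L)) {
    stop("occupancies must be positive integers", call. = FALSE)
  }
  if (!(env$w_d > 0) || !(env$w_o > 0)) {
    stop("w_d and w_o must be positive", call. = FALSE)
  }
  if (env$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (!(env$time_budget > 0)) stop("time_budget must be positive", call. = FALSE)
  invisible(env)
}

#' @export
print.dc_environment <- function(x, ...) {
  cat("<dc_environment> ", x$name, "\n", sep = "")
  cat("  destinations: ", paste(x$destinations, collapse = " "),
      " (origin ", x$origin, ")\n", sep = "")
  cat("  decisions tabulated:", nrow(x$occupancy_table), "\n")
  cat(sprintf("  w_d = %g, w_o = %g, eps ~ N(%g, %g^2), budget = %g min\n",
              x$w_d, x$w_o, x$noise_mu, x$noise_sigma, x$time_budget))
  if (!is.null(x$noise_table)) cat("  noise realized (shared across participants)\n")
  invisible(x)
}

#' Hypothetical time elapsed by a transition
#'
#' Computes `w_d * d + w_o * o + noise_value` for moving from `position`
#' to `destination` at the given decision index. The noise value is
#' supplied by the caller so that the noise realisation policy (shared
#' across participants versus fresh per participant) stays under the
#' caller's control; see [realize_noise()].
#'
#' @param env A [environment_spec()] object.
#' @param position Current position label (origin or a destination).
#' @param destination Destination label being evaluated; must differ
#'   from `position`.
#' @param decision_index Decision number (1-based row of the occupancy
#'   table).
#' @param noise_value Noise in minutes added to the deterministic cost.
#' @return Elapsed hypothetical minutes (numeric scalar).
#' @export
elapsed_time <- function(env, position, destination, decision_index,
                         noise_value = 0) {
  stopifnot(inherits(env, "dc_environment"))
  if (identical(position, destination)) {
    stop("destination must differ from current position", call. = FALSE)
  }
  if (!position %in% rownames(env$distance_table)) {
    stop("unknown position label: ", position, call. = FALSE)
  }
  if (!destination %in% colnames(env$distance_table)) {
    stop("unknown destination label: ", destination, call. = FALSE)
  }
  if (decision_index < 1 || decision_index > nrow(env$occupancy_table)) {
    stop("occupancy_table has no row for decision index ", decision_index,
         call. = FALSE)
  }
  d <- env$distance_table[position, destination]
  o <- env$occupancy_table[decision_index, destination]
  unname(env$w_d * d + env$w_o * o + noise_value)
}

#' Alternatives available at a decision
#'
#' Under the `shrinking` policy (the experiment's no-revisit rule) the
#' choice set is all destinations minus those already visited; under
#' `full` every destination remains available at every decision.
#'
#' @param env A [environment_spec()] object.
#' @param visited Character vector of destinations already visited, in
#'   order (no duplicates).
#' @param policy `"shrinking"` (default) or `"full"`.
#' @return Character vector of available destination labels.
#' @export
available_alternatives <- function(env, visited = character(),
                                   policy = c("shrinking", "full")) {
  stopifnot(inherits(env, "dc_environment"))
  policy <- match.arg(policy)
  visited <- as.character(visited)
  if (anyDuplicated(visited)) {
    stop("invalid trajectory: duplicated destination in visited", call. = FALSE)
  }
  bad <- setdiff(visited, env$destinations)
  if (length(bad)) {
    stop("unknown destination(s) in visited: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (policy == "full") env$destinations else setdiff(env$destinations, visited)
}

#' Realize the transition noise once per environment
#'
#' The virtual experiment is not simulated dynamically: the noisy
#' transition times are drawn once and reused for every participant, so
#' two participants making the same sequence of decisions experience
#' exactly the same elapsed times. This draws one `N(noise_mu,
#' noise_sigma^2)` value per (decision index, position, destination)
#' triple from a seeded generator and caches it on the environment.
#'
#' @param env A [environment_spec()] object.
#' @param seed Integer seed for the noise draws.
#' @return The environment with a `noise_table` array attached
#'   (decision index x position x destination).
#' @export
realize_noise <- function(env, seed = 1L) {
  stopifnot(inherits(env, "dc_environment"))
  positions <- rownames(env$distance_table)
  n_dec <- nrow(env$occupancy_table)
  n_pos <- length(positions)
  n_dst <- length(env$destinations)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  env$noise_table <- array(
    rnorm(n_dec * n_pos * n_dst, env$noise_mu, env$noise_sigma),
    dim = c(n_dec, n_pos, n_dst),
    dimnames = list(NULL, positions, env$destinations))
  env
}

#' Read and write environment definition files
#'
#' Environments are stored as plain YAML: destination labels, origin,
#' distance matrix (one row per position), occupancy matrix (one row per
#' decision index), cost weights, noise parameters and time budget. The
#' realized noise cache is never serialized.
#'
#' @param path File path.
#' @return `read_environment()` returns a `dc_environment`;
#'   `write_environment()` invisibly returns `path`.
#' @export
read_environment <- function(path) {
  y <- yaml::read_yaml(path)
  dm <- do.call(rbind, lapply(y$distance_table, as.integer))
  rownames(dm) <- names(y$distance_table)
  colnames(dm) <- y$destinations
  om <- do.call(rbind, lapply(y$occupancy_table, as.integer))
  colnames(om) <- y$destinations
  environment_spec(name = y$name, destinations = y$destinations,
                   origin = y$origin, distance_table = dm,
                   occupancy_table = om, w_d = y$w_d, w_o = y$w_o,
                   noise_mu = y$noise_mu, noise_sigma = y$noise_sigma,
                   time_budget = y$time_budget)
}

#' @rdname read_environment
#' @param env A [environment_spec()] object.
#' @export
write_environment <- function(env, path) {
  stopifnot(inherits(env, "dc_environment"))
  dt <- lapply(seq_len(nrow(env$distance_table)),
               function(i) as.integer(env$distance_table[i, ]))
  names(dt) <- rownames(env$distance_table)
  ot <- lapply(seq_len(nrow(env$occupancy_table)),
               function(i) as.integer(env$occupancy_table[i, ]))
  names(ot) <- paste0("decision_", seq_along(ot))
  yaml::write_yaml(
    list(name = env$name, destinations = as.list(env$destinations),
         origin = env$origin, distance_table = dt, occupancy_table = ot,
         w_d = env$w_d, w_o = env$w_o, noise_mu = env$noise_mu,
         noise_sigma = env$noise_sigma, time_budget = env$time_budget),
    path, precision = 17L)  # doubles survive the round-trip exactly
  invisible(path)
}

#' Bundled example environments
#'
#' Three ready-made environments mirroring the structure of the virtual
#' experiment: `"open"` and `"closed"` (60-minute budget, noise
#' `N(0, 2)`) and `"photo"` (15-minute budget, constant occupancy across
#' decisions, noise `N(1.5, 0.75)`; variances, not standard deviations).
#' The distance and occupancy tables are synthetic illustrative values,
#' not those of any particular study.
#'
#' @param name One of `"open"`, `"closed"`, `"photo"`.
#' @return A `dc_environment`.
#' @export
example_environment <- function(name = c("open", "closed", "photo")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "destchoice")
  if (!nzchar(path)) stop("bundled environment file not found", call. = FALSE)
  read_environment(path)
}
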