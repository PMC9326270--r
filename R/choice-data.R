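#' Canonical long-format choice data
#'
#' The package's central container is a long-format table with one row
#' per alternative per decision:
#'
#' * `participant_id` — participant identifier (character).
#' * `condition` — experimental condition label.
#' * `decision_index` — 1-based decision number within the trip.
#' * `alternative` — destination label of this row's alternative.
#' * `distance` — raw distance from the current position (arbitrary
#'   units).
#' * `occupancy` — raw head-count at the alternative.
#' * `desirability` — raw schedule desirability `q` (`NA` for
#'   conditions without schedules).
#' * `chosen` — 1 for the alternative actually chosen, 0 otherwise.
#' * `schedule` — the participant's schedule serialized as a string
#'   (`NA` if none); constant within a participant.
#'
#' Predictors are stored raw; per-decision normalisation (divide by the
#' maximum over the alternatives at that decision) is applied by the
#' model functions.
#'
#' @param df A data frame with the columns above (`schedule` optional).
#' @param policy Choice-set policy the data were recorded under;
#'   `"shrinking"` (no revisits, the experiment's rule) or `"full"`.
#' @return A `choice_data` object (a validated data frame).
#' @export
as_choice_data <- function(df, policy = c("shrinking", "full")) {
  policy <- match.arg(policy)
  required <- c("participant_id", "condition", "decision_index",
                "alternative", "distance", "occupancy", "chosen")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"desirability" %in% names(df)) df$desirability <- NA_real_
  if (!"schedule" %in% names(df)) df$schedule <- NA_character_
  df <- as.data.frame(df)[, c("participant_id", "condition", "decision_index",
                              "alternative", "distance", "occupancy",
                              "desirability", "chosen", "schedule")]
  df$participant_id <- as.character(df$participant_id)
  df$condition <- as.character(df$condition)
  df$decision_index <- as.integer(df$decision_index)
  df$alternative <- as.character(df$alternative)
  df$chosen <- as.integer(df$chosen)
  df$schedule <- as.character(df$schedule)
  validate_choice_data(df, policy)
  rownames(df) <- NULL
  structure(df, class = c("choice_data", "data.frame"),
            choice_set_policy = policy)
}

validate_choice_data <- function(df, policy) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$distance < 0, na.rm = TRUE) ||
      any(df$occupancy < 0, na.rm = TRUE)) {
    stop("distance and occupancy must be non-negative", call. = FALSE)
  }
  if (any(df$desirability < 0, na.rm = TRUE)) {
    stop("desirability must be non-negative", call. = FALSE)
  }
  key <- paste(df$participant_id, df$decision_index, df$alternative, sep = "\r")
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key))
    stop("duplicate (participant, decision, alternative) at row(s): ",
         paste(head(rows, 5L), collapse = ", "), call. = FALSE)
  }
  grp <- paste(df$participant_id, df$decision_index, sep = "\r")
  nch <- tapply(df$chosen, grp, sum)
  bad <- names(nch)[nch != 1L]
  if (length(bad)) {
    bad_rows <- which(grp %in% head(bad, 3L))
    stop("each decision must have exactly one chosen alternative; ",
         "violated near row(s): ", paste(head(bad_rows, 5L), collapse = ", "),
         call. = FALSE)
  }
  ch <- df[df$chosen == 1L, ]
  ndec <- tapply(ch$decision_index, ch$participant_id, length)
  if (any(ndec > 5L)) {
    stop("a trajectory may hold at most 5 decisions (participant ",
         names(ndec)[which(ndec > 5L)[1L]], ")", call. = FALSE)
  }
  if (policy == "shrinking") {
    dup <- tapply(ch$alternative, ch$participant_id,
                  function(x) anyDuplicated(x) > 0L)
    if (any(dup)) {
      pid <- names(dup)[which(dup)[1L]]
      rows <- which(df$participant_id == pid & df$chosen == 1L)
      stop("revisited destination under shrinking policy (participant ",
           pid, ", row(s) ", paste(rows, collapse = ", "), ")", call. = FALSE)
    }
  }
  invisible(df)
}

#' @export
print.choice_data <- function(x, ...) {
  n_p <- length(unique(x$participant_id))
  n_d <- sum(x$chosen)
  cat("<choice_data> ", n_p, " participants, ", n_d, " decisions, ",
      nrow(x), " alternative rows (policy: ",
      attr(x, "choice_set_policy"), ")\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' @export
`[.choice_data` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("participant_id", "chosen") %in% names(out))) {
    attr(out, "choice_set_policy") <- attr(x, "choice_set_policy")
    class(out) <- c("choice_data", "data.frame")
  }
  out
}

#' Ordered chosen destination sequences
#'
#' @param data A [as_choice_data()] object.
#' @return Named list: one character vector of chosen destinations per
#'   participant, ordered by decision index.
#' @export
chosen_sequences <- function(data) {
  stopifnot(inherits(data, "choice_data"))
  ch <- data[data$chosen == 1L, c("participant_id", "decision_index",
                                  "alternative")]
  ch <- ch[order(ch$participant_id, ch$decision_index), ]
  split(ch$alternative, ch$participant_id)
}

#' Per-participant schedules stored in a choice table
#'
#' @param data A [as_choice_data()] object.
#' @return Named list of schedules (character vectors of labels), `NULL`
#'   entries dropped.
#' @export
schedules_of <- function(data) {
  stopifnot(inherits(data, "choice_data"))
  s <- tapply(data$schedule, data$participant_id, function(x) x[1L])
  s <- s[!is.na(s)]
  lapply(as.list(s), parse_schedule)
}

#' Serialize and parse schedules
#'
#' A schedule is an ordered set of unique destination labels. In the
#' long-format table it is stored as a single string: labels are
#' concatenated directly when all are single characters (`"DEBAC"`),
#' otherwise joined with commas.
#'
#' @param labels Character vector of unique destination labels.
#' @return `format_schedule()` a string; `parse_schedule()` a character
#'   vector.
#' @export
format_schedule <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) return(NA_character_)
  if (anyDuplicated(labels)) stop("schedule labels must be unique", call. = FALSE)
  if (all(nchar(labels) == 1L)) paste(labels, collapse = "")
  else paste(labels, collapse = ",")
}

#' @rdname format_schedule
#' @param s A serialized schedule string.
#' @export
parse_schedule <- function(s) {
  if (length(s) != 1L || is.na(s)) return(character())
  if (grepl(",", s, fixed = TRUE)) strsplit(s, ",", fixed = TRUE)[[1L]]
  else strsplit(s, "", fixed = TRUE)[[1L]]
}

#' Model parameter vectors
#'
#' Parameters of the destination-choice model: `beta_occ` (occupancy /
#' busyness weight), `beta_dist` (distance weight) and, for schedule
#' conditions only, `beta_des` (desirability weight, constrained
#' non-negative because a schedule can only attract choices towards it).
#'
#' @param beta_occ,beta_dist Real-valued weights.
#' @param beta_des Non-negative desirability weight, or `NULL` for
#'   two-parameter models.
#' @return Named numeric vector of length 2 or 3.
#' @export
model_params <- function(beta_occ, beta_dist, beta_des = NULL) {
  p <- c(beta_occ = as.numeric(beta_occ), beta_dist = as.numeric(beta_dist))
  if (!is.null(beta_des)) {
    if (beta_des < 0) stop("beta_des must be >= 0", call. = FALSE)
    p <- c(p, beta_des = as.numeric(beta_des))
  }
  p
}
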