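#' Levenshtein distance between label sequences
#'
#' The minimal number of unit-cost edit operations (substitutions,
#' insertions, deletions; no transpositions) converting one destination
#' sequence into the other. Sequences are vectors of labels, so
#' multi-character labels compare as whole symbols. The metric is
#' symmetric, zero exactly on equal sequences, and bounded by the
#' longer sequence's length.
#'
#' @param a,b Character vectors (label sequences; may be empty).
#' @return Integer distance.
#' @seealso `levenshtein_many()` for many pairs at once.
#' @export
#' @examples
#' levenshtein(c("D", "E", "B", "A", "C"), c("D", "E", "B", "C", "A"))
levenshtein <- function(a, b) {
  levenshtein_many(list(as.character(a)), list(as.character(b)))[[1L]]
}

#' @rdname levenshtein
#' @param as,bs Lists of character vectors, paired elementwise.
#' @export
levenshtein_many <- function(as, bs) {
  stopifnot(is.list(as), is.list(bs), length(as) == length(bs))
  if (length(as) == 0L) return(integer())
  lab <- unique(unlist(c(as, bs), use.names = FALSE))
  enc <- function(x) match(as.character(x), lab)
  .lev_pairs(lapply(as, enc), lapply(bs, enc))
}

#' Schedule adherence of a cohort
#'
#' For every participant holding a schedule, computes the Levenshtein
#' distance between the planned schedule and the realised chosen
#' destination sequence. A distance of zero means the schedule was
#' followed exactly; realised sequences can be shorter than schedules
#' when the time budget ran out, which the metric absorbs as
#' deletions. Participants without a schedule are excluded (with a
#' message).
#'
#' @param data A [as_choice_data()] table whose `schedule` column is
#'   populated for the participants of interest.
#' @return An object of class `adherence_summary`: per-participant
#'   distances, their mean, and a distance histogram (counts at
#'   0, 1, 2, ...).
#' @export
adherence_summary <- function(data) {
  stopifnot(inherits(data, "choice_data"))
  seqs <- chosen_sequences(data)
  scheds <- schedules_of(data)
  no_sched <- setdiff(names(seqs), names(scheds))
  if (length(no_sched)) {
    message(length(no_sched), " participant(s) without a schedule excluded")
  }
  pids <- intersect(names(seqs), names(scheds))
  if (length(pids) == 0L) stop("no participant has a schedule", call. = FALSE)
  d <- levenshtein_many(scheds[pids], seqs[pids])
  names(d) <- pids
  histogram <- table(factor(d, levels = 0:max(c(d, 0L))))
  structure(list(distances = d, mean = mean(d), histogram = histogram,
                 n = length(d), excluded = no_sched),
            class = "adherence_summary")
}

#' @export
print.adherence_summary <- function(x, ...) {
  cat("<adherence_summary> ", x$n, " participants, mean distance ",
      round(x$mean, 3), "\n", sep = "")
  print(x$histogram)
  invisible(x)
}
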