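#' Schedule desirability of each destination
#'
#' A schedule `S` assigns desirability `q = exp(-p)` to the destination
#' at (1-based) position `p` of the *remaining* schedule, i.e. `S` with
#' already-visited destinations removed, order preserved. Under the
#' default `"rule"` variant, destinations absent from the schedule get
#' desirability zero. Under the `"worked_example"` variant, destinations
#' absent from the schedule are appended to its tail (in the order of
#' `all_destinations`) before positions are assigned, so every unvisited
#' destination receives a positive desirability; visited destinations
#' always get zero.
#'
#' @param schedule Character vector of unique destination labels (may be
#'   empty for no schedule).
#' @param visited Character vector of destinations already visited.
#' @param all_destinations Character vector of every destination label.
#' @param variant `"rule"` (default) or `"worked_example"`.
#' @return Named numeric vector of desirabilities over
#'   `all_destinations`.
#' @export
#' @examples
#' desirability_vector(c("A", "B", "C", "D", "E"), character(),
#'                     LETTERS[1:6], variant = "worked_example")
desirability_vector <- function(schedule, visited, all_destinations,
                                variant = c("rule", "worked_example")) {
  variant <- match.arg(variant)
  schedule <- as.character(schedule)
  visited <- as.character(visited)
  all_destinations <- as.character(all_destinations)
  bad <- setdiff(visited, all_destinations)
  if (length(bad)) {
    stop("visited contains unknown destination(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(schedule)) {
    stop("schedule labels must be unique", call. = FALSE)
  }
  q <- setNames(numeric(length(all_destinations)), all_destinations)
  remaining <- setdiff(schedule, visited)
  if (variant == "worked_example" && length(schedule) > 0L) {
    extras <- setdiff(all_destinations, union(schedule, visited))
    remaining <- c(remaining, extras)
  }
  if (length(remaining)) {
    q[remaining] <- exp(-seq_along(remaining))
  }
  q
}

#' Normalise predictor values within one decision
#'
#' Each predictor (occupancy, distance, desirability) is normalised per
#' decision to `[0, 1]` by dividing by the maximum observed value over
#' the alternatives at that decision. If the maximum is zero (no
#' signal), all normalised values are zero.
#'
#' @param values Non-negative numeric vector, one entry per alternative.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_predictors <- function(values) {
  if (length(values) < 1L) stop("at least one alternative required", call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) {
    stop("predictor values must be non-negative", call. = FALSE)
  }
  m <- max(values)
  if (m == 0) values * 0 else values / m
}

#' Linear utility of an alternative
#'
#' `U = beta_occ * n_hat + beta_dist * d_hat (+ beta_des * q_hat)`,
#' where the predictors are the per-decision normalised occupancy,
#' distance and (for schedule models) desirability.
#'
#' @param params A [model_params()] vector (length 2 or 3).
#' @param n_hat,d_hat Normalised occupancy and distance in `[0, 1]`.
#' @param q_hat Normalised desirability; must be supplied exactly when
#'   `params` carries `beta_des`.
#' @return Numeric utility (vectorised over the predictors).
#' @export
utility <- function(params, n_hat, d_hat, q_hat = NULL) {
  has_des <- "beta_des" %in% names(params)
  if (has_des && is.null(q_hat)) {
    stop("params include beta_des but q_hat is missing", call. = FALSE)
  }
  if (!has_des && !is.null(q_hat)) {
    stop("q_hat supplied but params have no beta_des", call. = FALSE)
  }
  u <- params[["beta_occ"]] * n_hat + params[["beta_dist"]] * d_hat
  if (has_des) u <- u + params[["beta_des"]] * q_hat
  u
}

#' Multinomial-logit choice probabilities at one decision
#'
#' The probability of choosing alternative `i` is
#' `exp(U_i) / sum_j exp(U_j)` over the decision's choice set, computed
#' with a max-utility shift for overflow safety. Raw predictors are
#' normalised per decision unless `normalized = TRUE`.
#'
#' @param params A [model_params()] vector.
#' @param distance,occupancy Raw (or normalised) predictor vectors, one
#'   entry per alternative.
#' @param desirability Raw (or normalised) desirability vector; required
#'   exactly when `params` carries `beta_des`.
#' @param labels Optional alternative labels for the result's names.
#' @param normalized Set `TRUE` if the inputs are already normalised.
#' @return Numeric probability vector summing to one.
#' @export
choice_probabilities <- function(params, distance, occupancy,
                                 desirability = NULL, labels = NULL,
                                 normalized = FALSE) {
  if (length(distance) != length(occupancy)) {
    stop("predictor vectors must have equal length", call. = FALSE)
  }
  if (length(distance) < 1L) stop("at least one alternative required", call. = FALSE)
  if (!normalized) {
    distance <- normalize_predictors(distance)
    occupancy <- normalize_predictors(occupancy)
    if (!is.null(desirability)) desirability <- normalize_predictors(desirability)
  }
  u <- utility(params, occupancy, distance, desirability)
  u <- u - max(u)
  p <- exp(u)
  p <- p / sum(p)
  if (!is.null(labels)) names(p) <- labels
  p
}

#' Log-likelihood of a choice dataset
#'
#' Sums, over every decision in the data, the log-probability of the
#' chosen alternative under the multinomial-logit model. Each decision
#' is one data point. Predictors are normalised per decision before
#' evaluating utilities.
#'
#' @param params A [model_params()] vector; must carry `beta_des`
#'   exactly when the data carry desirabilities.
#' @param data A [as_choice_data()] table.
#' @return The log-likelihood (a non-positive number).
#' @export
log_likelihood <- function(params, data) {
  model <- if ("beta_des" %in% names(params)) "three_param" else "two_param"
  design <- mnl_design(data, model)
  mnl_loglik(as.numeric(params[c("beta_occ", "beta_dist",
                                 if (model == "three_param") "beta_des")]),
             design)
}

# ---- internal fast design ------------------------------------------------
# The long table is reshaped once into rectangular blocks grouped by
# choice-set size m: per block, n_dec x m matrices of per-decision
# normalised predictors, the chosen column index, and the participant of
# each decision row. All likelihood work (fits, bootstrap, permutations)
# runs on these matrices.

mnl_design <- function(data, model = c("two_param", "three_param")) {
  model <- match.arg(model)
  stopifnot(inherits(data, "choice_data"))
  if (nrow(data) == 0L) stop("empty choice data", call. = FALSE)
  if (model == "three_param" && anyNA(data$desirability)) {
    stop("three_param model requires desirability for every row", call. = FALSE)
  }
  df <- as.data.frame(data)
  ord <- order(df$participant_id, df$decision_index)
  df <- df[ord, ]
  g <- paste(df$participant_id, df$decision_index, sep = "\r")
  g <- factor(g, levels = unique(g))
  norm_by <- function(x) {
    mx <- ave(x, g, FUN = max)
    ifelse(mx == 0, 0, x / mx)
  }
  nhat <- norm_by(df$occupancy)
  dhat <- norm_by(df$distance)
  qhat <- if (model == "three_param") norm_by(df$desirability) else NULL
  sizes <- as.integer(table(g))
  first <- c(1L, cumsum(sizes)[-length(sizes)] + 1L)
  pid <- df$participant_id[first]
  chosen_pos <- integer(length(sizes))
  row_of <- rep.int(seq_along(sizes), sizes)
  pos_in_group <- sequence(sizes)
  sel <- df$chosen == 1L
  chosen_pos[row_of[sel]] <- pos_in_group[sel]
  blocks <- list()
  for (m in sort(unique(sizes))) {
    idx <- which(sizes == m)          # decision (group) indices of size m
    rows <- which(row_of %in% idx)    # long-table rows, ordered by group
    mk <- function(x) matrix(x[rows], ncol = m, byrow = TRUE)
    blocks[[as.character(m)]] <- list(
      m = m,
      N = mk(nhat), D = mk(dhat),
      Q = if (!is.null(qhat)) mk(qhat),
      chosen = cbind(seq_along(idx), chosen_pos[idx]),
      pid = pid[idx])
  }
  structure(list(blocks = blocks, model = model,
                 n_obs = length(sizes),
                 participants = unique(pid)),
            class = "mnl_design")
}

# subset a design to the decisions of the given participants (with
# multiplicity), used by the resampling routines
mnl_design_subset <- function(design, pids, rows_by_pid = NULL) {
  if (is.null(rows_by_pid)) rows_by_pid <- mnl_rows_by_pid(design)
  blocks <- vector("list", length(design$blocks))
  names(blocks) <- names(design$blocks)
  n_obs <- 0L
  for (bn in names(design$blocks)) {
    b <- design$blocks[[bn]]
    rows <- unlist(rows_by_pid[[bn]][pids], use.names = FALSE)
    if (is.null(rows) || length(rows) == 0L) next
    nb <- list(m = b$m,
               N = b$N[rows, , drop = FALSE],
               D = b$D[rows, , drop = FALSE],
               Q = if (!is.null(b$Q)) b$Q[rows, , drop = FALSE],
               chosen = cbind(seq_along(rows), b$chosen[rows, 2L]),
               pid = b$pid[rows])
    n_obs <- n_obs + length(rows)
    blocks[[bn]] <- nb
  }
  blocks <- blocks[!vapply(blocks, is.null, logical(1L))]
  structure(list(blocks = blocks, model = design$model, n_obs = n_obs,
                 participants = unique(pids)),
            class = "mnl_design")
}

mnl_rows_by_pid <- function(design) {
  lapply(design$blocks,
         function(b) split(seq_along(b$pid), factor(b$pid)))
}

mnl_loglik <- function(beta, design) {
  ll <- 0
  for (b in design$blocks) {
    U <- beta[1L] * b$N + beta[2L] * b$D
    if (!is.null(b$Q)) U <- U + beta[3L] * b$Q
    rmax <- U[, 1L]
    if (b$m > 1L) for (j in 2:b$m) rmax <- pmax(rmax, U[, j])
    Z <- rowSums(exp(U - rmax))
    ll <- ll + sum(U[b$chosen] - rmax - log(Z))
  }
  ll
}

mnl_grad <- function(beta, design) {
  k <- if (design$model == "three_param") 3L else 2L
  g <- numeric(k)
  for (b in design$blocks) {
    U <- beta[1L] * b$N + beta[2L] * b$D
    if (!is.null(b$Q)) U <- U + beta[3L] * b$Q
    rmax <- U[, 1L]
    if (b$m > 1L) for (j in 2:b$m) rmax <- pmax(rmax, U[, j])
    E <- exp(U - rmax)
    P <- E / rowSums(E)
    g[1L] <- g[1L] + sum(b$N[b$chosen]) - sum(P * b$N)
    g[2L] <- g[2L] + sum(b$D[b$chosen]) - sum(P * b$D)
    if (k == 3L) g[3L] <- g[3L] + sum(b$Q[b$chosen]) - sum(P * b$Q)
  }
  g
}
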