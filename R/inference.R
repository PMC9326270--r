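#' Bootstrap confidence intervals for model parameters
#'
#' Resamples units (whole participants by default, preserving
#' within-participant dependence, or single decisions) with replacement
#' to the original unit count, refits the model on each replicate, and
#' returns percentile intervals at `(1 - level)/2` and `1 - (1 -
#' level)/2`. Replicates that fail to converge are redrawn, up to a
#' retry cap of `10 * B`; exceeding the cap flags the result.
#'
#' @param data A [as_choice_data()] table.
#' @param model `"two_param"` or `"three_param"`.
#' @param B Number of bootstrap replicates (the study-scale default is
#'   10000).
#' @param level Confidence level (default 0.95).
#' @param unit `"participant"` (default) or `"decision"`.
#' @param seed Integer seed for the resampling.
#' @param method Optimiser passed to the refits; `"L-BFGS-B"` (default
#'   here) uses the analytic gradient for speed.
#' @param bound Parameter box half-width (see [fit_mle()]).
#' @return An object of class `bootstrap_ci`: the point estimates, a
#'   `k x 2` matrix of percentile interval endpoints, the `B x k`
#'   replicate estimates, and the settings used.
#' @export
bootstrap_ci <- function(data, model = c("two_param", "three_param"),
                         B = 10000L, level = 0.95,
                         unit = c("participant", "decision"),
                         seed = 1L, method = "L-BFGS-B", bound = 20) {
  model <- match.arg(model)
  unit <- match.arg(unit)
  stopifnot(B >= 1L)
  design <- mnl_design(data, model)
  point <- fit_mnl_design(design, method = method, bound = bound)
  k <- point$k
  if (unit == "participant") {
    units <- design$participants
    rows_by_pid <- mnl_rows_by_pid(design)
    draw <- function() {
      pids <- sample(units, length(units), replace = TRUE)
      mnl_design_subset(design, pids, rows_by_pid)
    }
  } else {
    # relabel every decision as its own unit and resample those
    dec_design <- decision_unit_design(design)
    units <- dec_design$participants
    rows_by_pid <- mnl_rows_by_pid(dec_design)
    draw <- function() {
      ids <- sample(units, length(units), replace = TRUE)
      mnl_design_subset(dec_design, ids, rows_by_pid)
    }
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  est <- matrix(NA_real_, nrow = B, ncol = k,
                dimnames = list(NULL, names(point$params)))
  tries <- 0L
  flagged <- FALSE
  b <- 1L
  while (b <= B) {
    tries <- tries + 1L
    if (tries > 10L * B) {
      flagged <- TRUE
      break
    }
    f <- fit_mnl_design(draw(), method = method, bound = bound)
    if (!f$converged) next
    est[b, ] <- f$params
    b <- b + 1L
  }
  alpha <- (1 - level) / 2
  ci <- t(apply(est, 2L, quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  structure(list(estimate = point$params, ci = ci, replicates = est,
                 B = B, level = level, unit = unit, seed = seed,
                 flagged = flagged, n_draws = tries),
            class = "bootstrap_ci")
}

# give every decision its own unit id so decision-level resampling can
# reuse the participant-subsetting machinery
decision_unit_design <- function(design) {
  i <- 0L
  for (bn in names(design$blocks)) {
    n <- nrow(design$blocks[[bn]]$N)
    design$blocks[[bn]]$pid <- as.character(i + seq_len(n))
    i <- i + n
  }
  design$participants <- as.character(seq_len(i))
  design
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat("<bootstrap_ci> ", x$B, " replicates, ", x$level * 100,
      "% percentile intervals (unit: ", x$unit, ", seed ", x$seed, ")\n",
      sep = "")
  out <- cbind(estimate = x$estimate, x$ci)
  print(round(out, 3))
  if (x$flagged) cat("  WARNING: retry cap exceeded; intervals incomplete\n")
  invisible(x)
}

#' Permutation test on between-condition parameter differences
#'
#' Tests whether two experimental conditions share the same choice-model
#' parameters. The statistic is the sum of squared differences of the
#' per-group parameter estimates. The null distribution is built by
#' randomly re-allocating participants between the two groups, keeping
#' each group's participant count (and hence the overall amount of data
#' per condition) fixed, and refitting both models. The p-value is the
#' proportion of permuted statistics greater than or equal to the
#' observed one (ties count as exceeding), floored at `1/n_perm`.
#'
#' @param group_a,group_b [as_choice_data()] tables for the two
#'   conditions.
#' @param model `"two_param"` or `"three_param"` (fitted to both).
#' @param n_perm Number of permutations (study-scale default 10000).
#' @param seed Integer seed.
#' @param method,bound Optimiser settings for the refits.
#' @return An object of class `permutation_test`: observed statistic,
#'   permuted statistics, p-value, settings.
#' @export
permutation_test <- function(group_a, group_b,
                             model = c("two_param", "three_param"),
                             n_perm = 10000L, seed = 1L,
                             method = "L-BFGS-B", bound = 20) {
  model <- match.arg(model)
  stopifnot(inherits(group_a, "choice_data"), inherits(group_b, "choice_data"))
  if (nrow(group_a) == 0L || nrow(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  da <- mnl_design(group_a, model)
  db <- mnl_design(group_b, model)
  fa <- fit_mnl_design(da, method = method, bound = bound)
  fb <- fit_mnl_design(db, method = method, bound = bound)
  observed <- sum((fa$params - fb$params)^2)
  # pool with disambiguated participant ids; sort for label-swap symmetry
  pool_a <- as.data.frame(group_a)
  pool_a$participant_id <- paste0("a:", pool_a$participant_id)
  pool_b <- as.data.frame(group_b)
  pool_b$participant_id <- paste0("b:", pool_b$participant_id)
  pooled <- as_choice_data(rbind(pool_a, pool_b),
                           policy = attr(group_a, "choice_set_policy"))
  design <- mnl_design(pooled, model)
  rows_by_pid <- mnl_rows_by_pid(design)
  pids <- sort(design$participants)
  n_small <- min(length(da$participants), length(db$participants))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats <- numeric(n_perm)
  i <- 1L
  tries <- 0L
  flagged <- FALSE
  while (i <= n_perm) {
    tries <- tries + 1L
    if (tries > 10L * n_perm) {
      flagged <- TRUE
      stats <- stats[seq_len(i - 1L)]
      break
    }
    grp1 <- sample(pids, n_small)
    f1 <- fit_mnl_design(mnl_design_subset(design, grp1, rows_by_pid),
                         method = method, bound = bound)
    f2 <- fit_mnl_design(mnl_design_subset(design, setdiff(pids, grp1),
                                           rows_by_pid),
                         method = method, bound = bound)
    if (!f1$converged || !f2$converged) next
    stats[i] <- sum((f1$params - f2$params)^2)
    i <- i + 1L
  }
  p <- max(mean(stats >= observed), 1 / n_perm)
  structure(list(observed = observed, p_value = p, perm_stats = stats,
                 n_perm = n_perm, seed = seed, model = model,
                 estimates = list(a = fa$params, b = fb$params),
                 flagged = flagged),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("<permutation_test> sum-of-squared parameter differences\n")
  cat(sprintf("  observed = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$observed, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Likelihood-ratio test between nested model fits
#'
#' Tests whether the richer model (typically the three-parameter model
#' with the desirability term) significantly improves fit over the
#' nested one on the same data. The statistic is
#' `2 (logLik_full - logLik_nested)`, referred to the upper tail of a
#' chi-squared distribution with `df = k_full - k_nested`. Because
#' `beta_des` is constrained to the boundary `>= 0`, the asymptotic
#' null is really the mixture `0.5 chi2_0 + 0.5 chi2_1`; set
#' `boundary_mixture = TRUE` to use it (the plain chi-squared reference
#' is the conservative default).
#'
#' @param fit_full,fit_nested [fit_mle()] results on the same data, the
#'   nested model's parameters a subset of the full model's.
#' @param boundary_mixture Use the boundary-corrected mixture null.
#' @return An object of class `lr_test` with `statistic`, `df`,
#'   `p_value`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_nested,
                                  boundary_mixture = FALSE) {
  stopifnot(inherits(fit_full, "mnl_fit"), inherits(fit_nested, "mnl_fit"))
  if (fit_full$k <= fit_nested$k) {
    stop("fit_full must have more parameters than fit_nested", call. = FALSE)
  }
  if (fit_full$n_obs != fit_nested$n_obs) {
    stop("fits must be computed on the same data", call. = FALSE)
  }
  stat <- 2 * (fit_full$logLik - fit_nested$logLik)
  if (stat < -1e-6) {
    stop("nested log-likelihood exceeds the full model's; refit the full ",
         "model with init seeded at the nested solution", call. = FALSE)
  }
  stat <- max(stat, 0)
  df <- fit_full$k - fit_nested$k
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  if (boundary_mixture && df == 1L) {
    p <- if (stat == 0) 1 else 0.5 * pchisq(stat, 1L, lower.tail = FALSE)
  }
  structure(list(statistic = stat, df = df, p_value = p,
                 boundary_mixture = boundary_mixture),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("<lr_test> chi2(%d) = %.3f, p = %.4g%s\n", x$df, x$statistic,
              x$p_value,
              if (x$boundary_mixture) " (boundary mixture null)" else ""))
  invisible(x)
}
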