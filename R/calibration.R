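#' Maximum-likelihood calibration of the destination-choice model
#'
#' Fits the multinomial-logit model to a choice dataset by maximising
#' the log-likelihood with [stats::optim()]. The default optimiser is
#' the derivative-free Nelder-Mead simplex (relative tolerance `1e-8`,
#' at most 2000 iterations); `method = "L-BFGS-B"` uses the analytic
#' gradient and native box constraints and is preferred inside
#' resampling loops. Parameters are box-constrained to
#' `[-bound, bound]` and `beta_des` additionally to be non-negative;
#' under Nelder-Mead the box is enforced by clip-and-penalise. The
#' likelihood is concave, so both methods find the same optimum away
#' from the bounds.
#'
#' @param data A [as_choice_data()] table (non-empty).
#' @param model `"two_param"` (occupancy + distance) or `"three_param"`
#'   (+ desirability; requires schedule desirabilities in the data).
#' @param init Starting values; defaults to `c(0, 0)` or
#'   `c(0, 0, 0.1)`.
#' @param bound Half-width of the parameter box (default 20); generous
#'   enough for per-individual fits on a handful of decisions, where
#'   perfect separation would otherwise send estimates to infinity.
#' @param method `"Nelder-Mead"` (default) or `"L-BFGS-B"`.
#' @return An object of class `mnl_fit`: calibrated parameters,
#'   maximised log-likelihood, number of decisions (`n_obs`), number of
#'   free parameters (`k`), `aic = 2k - 2 logLik`, convergence flag and
#'   optimiser metadata. Non-convergence is flagged, not thrown.
#' @export
fit_mle <- function(data, model = c("two_param", "three_param"),
                    init = NULL, bound = 20,
                    method = c("Nelder-Mead", "L-BFGS-B")) {
  model <- match.arg(model)
  method <- match.arg(method)
  design <- mnl_design(data, model)
  fit_mnl_design(design, init = init, bound = bound, method = method)
}

# the worker: everything that refits (bootstrap, permutations,
# per-individual calibration) calls this on a prebuilt design
fit_mnl_design <- function(design, init = NULL, bound = 20,
                           method = "Nelder-Mead") {
  k <- if (design$model == "three_param") 3L else 2L
  if (is.null(init)) init <- if (k == 3L) c(0, 0, 0.1) else c(0, 0)
  init <- as.numeric(init)
  stopifnot(length(init) == k)
  lower <- c(-bound, -bound, 0)[seq_len(k)]
  upper <- rep(bound, k)
  if (method == "L-BFGS-B") {
    opt <- optim(init, fn = function(b) -mnl_loglik(b, design),
                 gr = function(b) -mnl_grad(b, design),
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 2000L, factr = 1e4))
    par <- opt$par
    converged <- opt$convergence == 0L
  } else {
    penalised <- function(b) {
      bc <- pmin(pmax(b, lower), upper)
      -mnl_loglik(bc, design) + 1e4 * sum((b - bc)^2)
    }
    opt <- optim(init, penalised, method = "Nelder-Mead",
                 control = list(maxit = 2000L, reltol = 1e-8))
    par <- pmin(pmax(opt$par, lower), upper)
    converged <- opt$convergence == 0L
  }
  ll <- mnl_loglik(par, design)
  params <- setNames(par, c("beta_occ", "beta_dist",
                            if (k == 3L) "beta_des"))
  structure(list(params = params, logLik = ll, n_obs = design$n_obs,
                 k = k, aic = 2 * k - 2 * ll, converged = converged,
                 model = design$model, init = init, method = method,
                 counts = opt$counts, bound = bound),
            class = "mnl_fit")
}

#' @export
print.mnl_fit <- function(x, ...) {
  cat("<mnl_fit> ", x$model, " multinomial logit (",
      x$n_obs, " decisions)\n", sep = "")
  print(round(x$params, 4))
  cat(sprintf("  logLik = %.3f, k = %d, AIC = %.1f (%s, %s)\n",
              x$logLik, x$k, x$aic, x$method,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
logLik.mnl_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.mnl_fit <- function(object, ...) object$params

#' AIC of the random (zero-parameter) choice model
#'
#' The reference model fixes all parameters at zero, so every available
#' alternative is equally likely: the log-likelihood is
#' `sum_j log(1 / m_j)`, with `m_j` the number of alternatives at
#' decision `j`. Under the `"shrinking"` policy `m_j` is the recorded
#' choice-set size; under `"full"` every decision offers all `m`
#' destinations, giving the closed form `2 N log(m) + 2 k_random`.
#'
#' @param data A [as_choice_data()] table.
#' @param policy `"shrinking"` or `"full"`.
#' @param k_random Parameter count charged to the random model
#'   (default 0).
#' @param n_alternatives Total number of destinations for the `"full"`
#'   policy; defaults to the number of distinct alternatives in `data`.
#' @return The AIC (numeric scalar).
#' @export
random_model_aic <- function(data, policy = c("shrinking", "full"),
                             k_random = 0L, n_alternatives = NULL) {
  stopifnot(inherits(data, "choice_data"))
  if (nrow(data) == 0L) stop("empty choice data", call. = FALSE)
  policy <- match.arg(policy)
  g <- paste(data$participant_id, data$decision_index, sep = "\r")
  if (policy == "full") {
    if (is.null(n_alternatives)) {
      n_alternatives <- length(unique(data$alternative))
    }
    n_dec <- length(unique(g))
    ll <- -n_dec * log(n_alternatives)
  } else {
    m_j <- as.integer(table(g))
    ll <- -sum(log(m_j))
  }
  2 * k_random - 2 * ll
}
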