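#' Normalised cumulative distance or occupancy per participant
#'
#' Sums the chosen alternative's raw distance (or occupancy) over a
#' participant's decisions and divides by the number of decisions that
#' participant made, so trips cut short by the time budget remain
#' comparable to complete ones.
#'
#' @param data A [as_choice_data()] table.
#' @param quantity `"distance"` or `"occupancy"`.
#' @return Named numeric vector, one value per participant.
#' @export
normalized_cumulative <- function(data, quantity = c("distance", "occupancy")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(data, "choice_data"))
  ch <- data[data$chosen == 1L, ]
  if (nrow(ch) == 0L) stop("no decisions in data", call. = FALSE)
  v <- tapply(ch[[quantity]], ch$participant_id, mean)
  setNames(as.numeric(v), names(v))
}

#' Threshold between two modes of a distribution
#'
#' Histograms the values into `bins` equal-width bins, lightly smooths
#' the counts with a (1, 2, 1)/4 kernel to suppress single-bin sampling
#' wiggles, and looks for multi-modality. Local maxima of the smoothed
#' counts are candidate modes; a mode must reach at least `min_height`
#' of the tallest bin, and two modes only count as separate if some bin
#' between them drops below `valley_depth` times the smaller of the two
#' mode counts. Among qualifying pairs the two highest modes win, and
#' the returned threshold is the midpoint of their bin centres. If no
#' qualifying pair exists the distribution is treated as unimodal and
#' `NULL` is returned (no clustering attempted).
#'
#' @param values Numeric vector (at least 10 values).
#' @param bins Number of histogram bins (default 20).
#' @param min_height Minimum mode height as a fraction of the tallest
#'   bin (default 0.2).
#' @param valley_depth Maximum valley height as a fraction of the
#'   smaller mode (default 0.5).
#' @return The threshold (numeric scalar) or `NULL`.
#' @export
estimate_bimodal_threshold <- function(values, bins = 20L,
                                       min_height = 0.2,
                                       valley_depth = 0.5) {
  values <- values[is.finite(values)]
  if (length(values) < 10L) stop("need at least 10 values", call. = FALSE)
  rng <- range(values)
  if (rng[1L] == rng[2L]) return(NULL)  # all mass in one bin
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  raw <- tabulate(idx, nbins = bins)
  # reflect at the edges so the kernel keeps total mass comparable
  counts <- as.numeric(stats::filter(c(raw[1L], raw, raw[bins]),
                                     c(1, 2, 1) / 4)[2:(bins + 1L)])
  centres <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
  # collapse plateaus, then flag runs higher than both neighbours
  peaks <- local_maxima(counts)
  peaks <- peaks[counts[peaks] >= min_height * max(counts)]
  if (length(peaks) < 2L) return(NULL)
  ord <- peaks[order(counts[peaks], decreasing = TRUE)]
  for (a_i in seq_len(length(ord) - 1L)) {
    for (b_i in (a_i + 1L):length(ord)) {
      i <- min(ord[a_i], ord[b_i])
      j <- max(ord[a_i], ord[b_i])
      if (j - i < 2L) next
      valley <- min(counts[(i + 1L):(j - 1L)])
      if (valley < valley_depth * min(counts[i], counts[j])) {
        return((centres[i] + centres[j]) / 2)
      }
    }
  }
  NULL
}

local_maxima <- function(counts) {
  n <- length(counts)
  runs <- rle(counts)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- integer()
  for (r in seq_along(runs$values)) {
    left <- if (r == 1L) -Inf else runs$values[r - 1L]
    right <- if (r == length(runs$values)) -Inf else runs$values[r + 1L]
    if (runs$values[r] > left && runs$values[r] > right) {
      out <- c(out, as.integer(round((starts[r] + ends[r]) / 2)))
    }
  }
  out
}

#' Assign participants to clusters by a threshold
#'
#' @param values Named numeric vector (participant id -> value), e.g.
#'   from [normalized_cumulative()].
#' @param threshold Finite threshold; values below it go to cluster
#'   `"below"`, values at or above to `"above"`.
#' @param quantity Optional name of the thresholded quantity (metadata).
#' @return A `cluster_assignment` data frame (`participant_id`,
#'   `cluster`) with method metadata attached. An empty side is flagged
#'   with a warning.
#' @export
threshold_clusters <- function(values, threshold, quantity = NULL) {
  stopifnot(is.finite(threshold))
  cl <- ifelse(values < threshold, "below", "above")
  if (length(unique(cl)) < 2L) {
    warning("threshold produces an empty cluster", call. = FALSE)
  }
  structure(data.frame(participant_id = names(values), cluster = cl,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("cluster_assignment", "data.frame"),
            method = "threshold", threshold = threshold,
            quantity = quantity)
}

#' Per-individual model calibration
#'
#' Fits the choice model separately to each participant's decisions.
#' With at most five decisions per participant, estimates are noisy and
#' perfect separation is common, so the box constraint of [fit_mle()]
#' keeps every estimate finite. Participants whose fit does not
#' converge are flagged and excluded (with a message).
#'
#' @param data A [as_choice_data()] table.
#' @param model `"two_param"` or `"three_param"`.
#' @param bound Parameter box half-width (default 20).
#' @param method Optimiser (default `"L-BFGS-B"` for speed).
#' @return A numeric matrix of estimates (participants x parameters)
#'   with an `excluded` attribute listing non-converged participants.
#' @export
per_individual_fits <- function(data, model = c("two_param", "three_param"),
                                bound = 20, method = "L-BFGS-B") {
  model <- match.arg(model)
  design <- mnl_design(data, model)
  rows_by_pid <- mnl_rows_by_pid(design)
  pids <- design$participants
  k <- if (model == "three_param") 3L else 2L
  est <- matrix(NA_real_, nrow = length(pids), ncol = k,
                dimnames = list(pids, c("beta_occ", "beta_dist",
                                        if (k == 3L) "beta_des")))
  excluded <- character()
  for (p in pids) {
    f <- fit_mnl_design(mnl_design_subset(design, p, rows_by_pid),
                        bound = bound, method = method)
    if (f$converged) est[p, ] <- f$params else excluded <- c(excluded, p)
  }
  if (length(excluded)) {
    message(length(excluded), " participant(s) excluded (non-convergence)")
    est <- est[!rownames(est) %in% excluded, , drop = FALSE]
  }
  attr(est, "excluded") <- excluded
  est
}

#' Hierarchical clustering of per-individual parameter estimates
#'
#' Agglomerative clustering (complete linkage by default, matching
#' `hclust`'s default) of the Euclidean distances between participants'
#' parameter estimates. Clusters are the subtrees below `cut_height`,
#' or exactly `k` clusters if `k` is given instead.
#'
#' @param estimates Matrix from [per_individual_fits()] (participants x
#'   parameters).
#' @param cut_height Dendrogram cut height (e.g. 1.75).
#' @param k Number of clusters (alternative to `cut_height`).
#' @param linkage Agglomeration method (default `"complete"`).
#' @return A `cluster_assignment` data frame with method metadata and
#'   the `hclust` tree attached.
#' @export
hierarchical_clusters <- function(estimates, cut_height = NULL, k = NULL,
                                  linkage = "complete") {
  stopifnot(is.matrix(estimates), nrow(estimates) >= 2L)
  if (is.null(cut_height) && is.null(k)) {
    stop("supply cut_height or k", call. = FALSE)
  }
  tree <- hclust(dist(estimates, method = "euclidean"), method = linkage)
  cl <- if (!is.null(k)) cutree(tree, k = k) else cutree(tree, h = cut_height)
  structure(data.frame(participant_id = rownames(estimates),
                       cluster = as.character(cl),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("cluster_assignment", "data.frame"),
            method = "hierarchical", linkage = linkage,
            cut_height = cut_height, k = k, tree = tree)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> method:", attr(x, "method"), "\n")
  print(table(x$cluster))
  invisible(x)
}

#' Compare a clustered model against the aggregate model
#'
#' Calibrates the choice model on each cluster separately and on all
#' participants together. The clustered model's AIC is the sum of the
#' per-cluster AICs; a smaller clustered AIC indicates that the cohort
#' contains distinct behavioural groups worth modelling separately.
#' Clusters with no participants in the data are skipped with a
#' warning.
#'
#' @param data A [as_choice_data()] table.
#' @param assignment A `cluster_assignment` covering every participant
#'   in `data`.
#' @param model `"two_param"` or `"three_param"`.
#' @param method Optimiser for the fits.
#' @return An object of class `cluster_comparison`: per-cluster fits,
#'   summed clustered AIC, aggregate fit and AIC.
#' @export
clustered_model_comparison <- function(data,
                                       assignment,
                                       model = c("two_param", "three_param"),
                                       method = "Nelder-Mead") {
  model <- match.arg(model)
  stopifnot(inherits(assignment, "cluster_assignment"))
  pids <- unique(data$participant_id)
  missing_pids <- setdiff(pids, assignment$participant_id)
  if (length(missing_pids)) {
    stop("assignment lacks participant(s): ",
         paste(head(missing_pids, 5L), collapse = ", "), call. = FALSE)
  }
  aggregate_fit <- fit_mle(data, model, method = method)
  cluster_fits <- list()
  for (cl in sort(unique(assignment$cluster))) {
    members <- assignment$participant_id[assignment$cluster == cl]
    sub <- data[data$participant_id %in% members, ]
    if (sum(sub$chosen) == 0L) {
      warning("cluster ", cl, " has no data; skipped", call. = FALSE)
      next
    }
    cluster_fits[[cl]] <- fit_mle(sub, model, method = method)
  }
  clustered_aic <- sum(vapply(cluster_fits, function(f) f$aic, numeric(1L)))
  structure(list(cluster_fits = cluster_fits,
                 clustered_aic = clustered_aic,
                 aggregate_fit = aggregate_fit,
                 aggregate_aic = aggregate_fit$aic,
                 sizes = table(assignment$cluster)),
            class = "cluster_comparison")
}

#' @export
print.cluster_comparison <- function(x, ...) {
  cat("<cluster_comparison>\n")
  for (cl in names(x$cluster_fits)) {
    f <- x$cluster_fits[[cl]]
    cat(sprintf("  cluster %-10s n_obs %4d  %s  AIC %.1f\n", cl, f$n_obs,
                paste(sprintf("%s=%.2f", names(f$params), f$params),
                      collapse = " "), f$aic))
  }
  cat(sprintf("  clustered AIC = %.1f vs aggregate AIC = %.1f\n",
              x$clustered_aic, x$aggregate_aic))
  invisible(x)
}
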