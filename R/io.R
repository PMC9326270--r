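#' Read and write long-format choice tables
#'
#' The canonical on-disk format is CSV with the columns of
#' [as_choice_data()]. `read_choice_data()` can adapt external data
#' whose headers differ via `mapping`, a named character vector from
#' canonical names to the file's column names (e.g.
#' `c(participant_id = "respondent")`). If an `attempt` column is
#' present, only first attempts are kept (repeat attempts of the task
#' are excluded from analysis). Rows violating the container's
#' invariants are rejected with row-numbered diagnostics.
#'
#' @param path File path.
#' @param mapping Optional named character vector renaming columns.
#' @param policy Choice-set policy of the recorded data.
#' @return `read_choice_data()` a [as_choice_data()] table (empty file
#'   gives an empty table with a warning); `write_choice_data()`
#'   invisibly `path`.
#' @export
read_choice_data <- function(path, mapping = NULL,
                             policy = c("shrinking", "full")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) {
    warning("empty choice file: ", path, call. = FALSE)
    df <- data.frame(participant_id = character(), condition = character(),
                     decision_index = integer(), alternative = character(),
                     distance = numeric(), occupancy = numeric(),
                     desirability = numeric(), chosen = integer(),
                     schedule = character(), stringsAsFactors = FALSE)
    return(as_choice_data(df, policy))
  }
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(df)) {
        stop("mapped column not in file: ", src, call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  if ("attempt" %in% names(df)) df <- df[df$attempt == 1, ]
  if ("schedule" %in% names(df)) {
    df$schedule <- as.character(df$schedule)
    df$schedule[is.na(df$schedule) | !nzchar(df$schedule)] <- NA_character_
  }
  as_choice_data(df, policy)
}

#' @rdname read_choice_data
#' @param data A [as_choice_data()] table.
#' @export
write_choice_data <- function(data, path) {
  stopifnot(inherits(data, "choice_data"))
  write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Configure the end-to-end analysis pipeline
#'
#' @param conditions Named list; each element is either a
#'   [as_choice_data()] table, a [cohort_spec()] (simulated on demand),
#'   or a file path read with [read_choice_data()]. Conditions whose
#'   data carry schedules are fitted with the three-parameter model,
#'   the rest with the two-parameter model.
#' @param comparisons List of length-2 character vectors naming
#'   condition pairs for permutation tests (default: none).
#' @param B Bootstrap replicates per condition (0 disables the
#'   bootstrap).
#' @param n_perm Permutations per comparison.
#' @param cluster_bins Histogram bins for threshold clustering.
#' @param cluster_cut Dendrogram cut height for hierarchical
#'   clustering.
#' @param seed Master seed; stage seeds are derived from it and logged.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(conditions, comparisons = list(),
                            B = 1000L, n_perm = 1000L,
                            cluster_bins = 20L, cluster_cut = 1.75,
                            seed = 1L) {
  stopifnot(is.list(conditions), length(names(conditions)) ==
              length(conditions))
  structure(list(conditions = conditions, comparisons = comparisons,
                 B = as.integer(B), n_perm = as.integer(n_perm),
                 cluster_bins = as.integer(cluster_bins),
                 cluster_cut = cluster_cut, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' For every condition: model calibration (two- or three-parameter as
#' the data dictate), random-model AIC, and (optionally) bootstrap
#' confidence intervals. Then: a likelihood-ratio test of the
#' desirability term for each schedule condition, permutation tests
#' for the configured condition pairs, both clustering procedures
#' (threshold clustering on normalised cumulative distance and
#' occupancy where bimodality is detected; hierarchical clustering of
#' per-individual estimates), and a schedule-adherence summary for
#' schedule conditions. A failing stage is isolated: its error message
#' is recorded and dependent stages are skipped.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with elements `fits`, `tests`,
#'   `clustering`, `adherence`, `notes`, and `seeds`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  notes <- character()
  note <- function(...) notes <<- c(notes, paste0(...))
  seeds <- list(master = config$seed)
  datasets <- list()
  for (nm in names(config$conditions)) {
    x <- config$conditions[[nm]]
    datasets[[nm]] <- tryCatch({
      if (inherits(x, "choice_data")) x
      else if (inherits(x, "cohort_spec")) simulate_cohort(x)$data
      else if (is.character(x)) read_choice_data(x)
      else stop("unsupported condition input")
    }, error = function(e) {
      note("condition ", nm, " failed to load: ", conditionMessage(e))
      NULL
    })
  }
  datasets <- datasets[!vapply(datasets, is.null, logical(1L))]

  fits <- list()
  for (nm in names(datasets)) {
    data <- datasets[[nm]]
    model <- if (any(!is.na(data$schedule))) "three_param" else "two_param"
    fits[[nm]] <- tryCatch({
      fit <- fit_mle(data, model)
      boot <- if (config$B > 0L) {
        seeds[[paste0("bootstrap_", nm)]] <- config$seed + 1000L + length(seeds)
        bootstrap_ci(data, model, B = config$B,
                     seed = seeds[[paste0("bootstrap_", nm)]])
      }
      list(model = model, fit = fit,
           random_aic_shrinking = random_model_aic(data, "shrinking"),
           random_aic_full = random_model_aic(data, "full"),
           bootstrap = boot)
    }, error = function(e) {
      note("fit stage failed for ", nm, ": ", conditionMessage(e))
      NULL
    })
  }

  tests <- list()
  for (nm in names(datasets)) {
    data <- datasets[[nm]]
    if (!any(!is.na(data$schedule))) next
    tests[[paste0("lrt_", nm)]] <- tryCatch({
      full <- fit_mle(data, "three_param")
      nested <- fit_mle(data, "two_param")
      likelihood_ratio_test(full, nested)
    }, error = function(e) {
      note("LRT failed for ", nm, ": ", conditionMessage(e))
      NULL
    })
  }
  for (cmp in config$comparisons) {
    key <- paste0("perm_", cmp[1L], "_vs_", cmp[2L])
    tests[[key]] <- tryCatch({
      if (!all(cmp %in% names(datasets))) stop("condition data missing")
      seeds[[key]] <- config$seed + 2000L + length(seeds)
      permutation_test(datasets[[cmp[1L]]], datasets[[cmp[2L]]],
                       model = "two_param", n_perm = config$n_perm,
                       seed = seeds[[key]])
    }, error = function(e) {
      note("permutation test ", key, " failed: ", conditionMessage(e))
      NULL
    })
  }

  clustering <- list()
  for (nm in names(datasets)) {
    data <- datasets[[nm]]
    model <- fits[[nm]]$model
    if (is.null(model)) next
    clustering[[nm]] <- tryCatch({
      out <- list()
      for (qty in c("distance", "occupancy")) {
        v <- normalized_cumulative(data, qty)
        thr <- estimate_bimodal_threshold(v, bins = config$cluster_bins)
        if (!is.null(thr)) {
          asg <- threshold_clusters(v, thr, quantity = qty)
          out[[paste0("threshold_", qty)]] <-
            list(threshold = thr,
                 comparison = clustered_model_comparison(data, asg, model))
        }
      }
      est <- per_individual_fits(data, model)
      if (nrow(est) >= 2L) {
        asg <- hierarchical_clusters(est, cut_height = config$cluster_cut)
        out$hierarchical <-
          list(assignment = asg,
               comparison = clustered_model_comparison(data, asg, model))
      }
      out
    }, error = function(e) {
      note("clustering failed for ", nm, ": ", conditionMessage(e))
      NULL
    })
  }

  adherence <- list()
  for (nm in names(datasets)) {
    data <- datasets[[nm]]
    if (!any(!is.na(data$schedule))) next
    adherence[[nm]] <- tryCatch(suppressMessages(adherence_summary(data)),
                                error = function(e) {
                                  note("adherence failed for ", nm, ": ",
                                       conditionMessage(e))
                                  NULL
                                })
  }

  structure(list(fits = fits, tests = tests, clustering = clustering,
                 adherence = adherence, notes = notes, seeds = seeds),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n== Model fits ==\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    if (is.null(f)) next
    cat("--", nm, "--\n")
    print(f$fit)
    cat(sprintf("  random AIC: %.1f (shrinking) / %.1f (full)\n",
                f$random_aic_shrinking, f$random_aic_full))
    if (!is.null(f$bootstrap)) print(f$bootstrap)
  }
  if (length(x$tests)) {
    cat("== Hypothesis tests ==\n")
    for (nm in names(x$tests)) {
      cat("--", nm, "--\n")
      if (!is.null(x$tests[[nm]])) print(x$tests[[nm]])
    }
  }
  if (length(x$clustering)) {
    cat("== Clustering ==\n")
    for (nm in names(x$clustering)) {
      for (k in names(x$clustering[[nm]])) {
        cat("--", nm, "/", k, "--\n")
        print(x$clustering[[nm]][[k]]$comparison)
      }
    }
  }
  if (length(x$adherence)) {
    cat("== Schedule adherence ==\n")
    for (nm in names(x$adherence)) {
      cat("--", nm, "--\n")
      print(x$adherence[[nm]])
    }
  }
  if (length(x$notes)) {
    cat("== Notes ==\n")
    cat(paste0("  ", x$notes, collapse = "\n"), "\n")
  }
  invisible(x)
}
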