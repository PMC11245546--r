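# --- plain-text IO -----------------------------------------------------------

#' Read and write ROI time-series TSV files
#'
#' One run per file: a `time_s` column followed by one column per ROI
#' (`roi_001..roi_P`), tab-separated.
#'
#' @param ts a [roi_timeseries()].
#' @param path file path.
#' @return `read_roi_tsv()` returns a [roi_timeseries()]; the TR is inferred
#'   from the `time_s` spacing unless given.
#' @export
write_roi_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  df <- data.frame(time_s = (seq_len(nrow(ts$data)) - 1) * ts$tr)
  mat <- as.data.frame(ts$data)
  names(mat) <- ts$roi_names
  utils::write.table(cbind(df, mat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_tsv
#' @param subject_id,run_label,tr metadata for the returned object; `tr`
#'   defaults to the `time_s` spacing.
#' @export
read_roi_tsv <- function(path, subject_id = "s01", run_label = "rest",
                         tr = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("missing 'time_s' column in ", path)
  if (is.null(tr)) tr <- stats::median(diff(df$time_s))
  roi_timeseries(as.matrix(df[names(df) != "time_s"]), tr = tr,
                 subject_id = subject_id, run_label = run_label,
                 roi_names = setdiff(names(df), "time_s"))
}

#' Write a state sequence as CSV
#'
#' Columns: subject, run, volume_index, time_s, label, distance.
#'
#' @param seq a `state_sequence` (from [predict.state_kmeans()]).
#' @param path file path.
#' @export
write_state_csv <- function(seq, path) {
  stopifnot(inherits(seq, "state_sequence"))
  utils::write.csv(data.frame(
    subject = seq$subject_id, run = seq$run_label,
    volume_index = seq_along(seq$labels), time_s = seq$times,
    label = seq$labels, distance = seq$distances), path, row.names = FALSE)
  invisible(path)
}

#' Persist and restore a pattern dictionary
#'
#' The dictionary is stored as a JSON bundle (centroids, pair index, fit
#' metadata) readable outside R.
#'
#' @param fit a [fit_states()] object.
#' @param path file path (`.json`).
#' @export
write_centroids_json <- function(fit, path) {
  stopifnot(inherits(fit, "state_kmeans"))
  jsonlite::write_json(list(
    k = fit$k, d = fit$d, centroids = fit$centroids,
    pair_index = fit$pair_index, inertia = fit$inertia,
    replicate_seeds = fit$replicate_seeds, n_train = fit$n), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centroids_json
#' @export
read_centroids_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(centroids = matrix(unlist(j$centroids), nrow = j$k),
         k = j$k, d = j$d,
         pair_index = if (!is.null(j$pair_index))
           matrix(as.integer(unlist(j$pair_index)), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))) else NULL,
         inertia = j$inertia, replicate_seeds = j$replicate_seeds,
         labels = NULL, distances = NULL, n = j$n_train,
         replicate_costs = numeric(0), cost_trace = numeric(0),
         iterations = NA_integer_, sources = NULL),
    class = "state_kmeans")
}

# --- orchestration -----------------------------------------------------------

#' Run the full analysis end to end
#'
#' Executes the stages in dependency order — simulate the study, fit the
#' pattern dictionary on pooled resting-state coherence, label the task
#' volumes with the rest-trained centroids, run the behavioral statistics
#' (detection-rate and RT mixed models, baseline comparisons, post-stimulus
#' and time-resolved occupancy, rating correlations), and optionally the
#' circular-shift surrogate control — writing each artifact plus a manifest
#' (master seed, child seeds, config hash) to `out_dir`. Runs are
#' deterministic under a fixed seed.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if needed); `NULL` keeps results
#'   in memory only.
#' @param seed master seed.
#' @param k patterns to fit, or `"select"` to run silhouette selection over
#'   `k_grid`.
#' @param k_grid candidate k values when `k = "select"`.
#' @param n_replicates k-means restarts.
#' @param surrogate also run the surrogate control.
#' @param dry_run print the stage plan and return it without computing or
#'   writing anything.
#' @return Object of class `pipeline_run` with elements `sim`, `fit`,
#'   `kselect`, `task_states`, `trials`, `rates`, `rate_model`, `baseline`,
#'   `rt_model`, `poststim`, `time_resolved`, `ratings_cor`, `surrogate`,
#'   `manifest` (or, for `dry_run`, the character stage plan).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = config$rng_seed,
                         k = config$n_states, k_grid = 3:7,
                         n_replicates = 20L, surrogate = FALSE,
                         dry_run = FALSE) {
  stopifnot(inherits(config, "phasestates_config"))
  stages <- c("simulate study", if (identical(k, "select"))
    "select k (silhouette)" else sprintf("fit %s rest states", k),
    "label task volumes", "behavioral statistics",
    if (surrogate) "surrogate control", "write report")
  if (dry_run) {
    cat("stage plan:\n", paste0("  ", seq_along(stages), ". ", stages,
                                collapse = "\n"), "\n")
    return(invisible(stages))
  }
  if (is.null(seed)) stop("supply 'seed' (or set rng_seed in the config)")
  seeds <- child_seeds(seed, 4L)

  sim <- simulate_study(config, seed = seeds[1L])

  rest_coh <- lapply(sim$subjects, function(s)
    coherence_series(instantaneous_phase(s$rest$ts)))
  kselect <- NULL
  if (identical(k, "select")) {
    kselect <- select_k(rest_coh, k_grid = k_grid,
                        n_replicates = n_replicates, seed = seeds[2L])
    fit <- kselect$fits[[as.character(kselect$best_k)]]
  } else {
    fit <- fit_states(rest_coh, k = k, n_replicates = n_replicates,
                      seed = seeds[2L])
  }

  task_states <- lapply(sim$subjects, function(s)
    lapply(s$task, function(tb)
      predict(fit, coherence_series(instantaneous_phase(tb$ts)))))
  names(task_states) <- vapply(sim$subjects, `[[`, "", "subject_id")
  states <- state_table(task_states)

  trials <- join_patterns(sim$trials, states)
  rates <- detection_rates(trials)
  rate_model <- fit_rate_model(detection_rates(trials, by_prev = TRUE),
                               include_prev = TRUE)
  baseline_rate <- rates$overall$rate[rates$overall$snr == "-9"]
  baseline <- compare_to_baseline(rates, baseline = baseline_rate)
  rt_model <- fit_rt_model(trials)
  poststim <- poststim_occupancy(trials, states)
  time_resolved <- time_resolved_occupancy(trials, states)
  ratings_cor <- ratings_correlation(block_occupancy(states), sim$ratings)

  sur <- NULL
  if (surrogate)
    sur <- surrogate_control(lapply(sim$subjects, function(s) s$rest$ts),
                             k = fit$k, n_replicates = n_replicates,
                             seed = seeds[3L])

  run <- structure(
    list(sim = sim, fit = fit, kselect = kselect, task_states = task_states,
         trials = trials, rates = rates, rate_model = rate_model,
         baseline = baseline, rt_model = rt_model, poststim = poststim,
         time_resolved = time_resolved, ratings_cor = ratings_cor,
         surrogate = sur, manifest = NULL),
    class = "pipeline_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    utils::write.csv(states, file.path(out_dir, "task_states.csv"),
                     row.names = FALSE)
    utils::write.csv(rates$cells, file.path(out_dir, "rate_cells.csv"),
                     row.names = FALSE)
    utils::write.csv(rate_model$term_tests,
                     file.path(out_dir, "rate_model_terms.csv"),
                     row.names = FALSE)
    utils::write.csv(rate_model$contrasts,
                     file.path(out_dir, "rate_model_contrasts.csv"),
                     row.names = FALSE)
    utils::write.csv(baseline, file.path(out_dir, "baseline_wilcoxon.csv"),
                     row.names = FALSE)
    utils::write.csv(rt_model$term_tests,
                     file.path(out_dir, "rt_model_terms.csv"),
                     row.names = FALSE)
    utils::write.csv(poststim$tests,
                     file.path(out_dir, "poststim_occupancy_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(time_resolved$tests,
                     file.path(out_dir, "time_resolved_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(ratings_cor, file.path(out_dir, "ratings_spearman.csv"),
                     row.names = FALSE)
    write_centroids_json(fit, file.path(out_dir, "centroids.json"))

    cfg_path <- file.path(out_dir, "config.json")
    cfg_json <- config
    cfg_json$state_templates <- NULL  # derivable from phase_offsets
    jsonlite::write_json(unclass(cfg_json), cfg_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    manifest <- list(master_seed = seed, child_seeds = seeds,
                     config_hash = unname(tools::md5sum(cfg_path)),
                     n_subjects = config$n_subjects, k = fit$k,
                     files = list.files(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    run$manifest <- manifest
    writeLines(utils::capture.output(pipeline_report(run)),
               file.path(out_dir, "report.txt"))
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d subjects, k = %d patterns\n",
              length(x$sim$subjects), x$fit$k))
  invisible(x)
}

#' Human-readable summary of a pipeline run
#'
#' Tabulates the dictionary summary, overall and per-pattern detection rates,
#' the mixed-model term tests, the occupancy comparisons and, when present,
#' the surrogate-control metrics. Sections whose inputs are missing are
#' marked absent.
#'
#' @param run a [run_pipeline()] result.
#' @return The run, invisibly; the report is printed.
#' @export
pipeline_report <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  section <- function(title) cat("\n== ", title, " ==\n", sep = "")
  section("Pattern dictionary")
  print(summary(run$fit))
  section("Detection rates by SNR")
  print(transform(run$rates$overall, rate = round(rate, 3)),
        row.names = FALSE)
  section("Threshold detection rate by pattern (SNR -9)")
  c9 <- run$rates$cells[run$rates$cells$snr == "-9", ]
  bp <- stats::aggregate(rate ~ pattern, data = c9, FUN = mean)
  print(transform(bp, rate = round(rate, 3)), row.names = FALSE)
  section("Detection-rate mixed model (arcsine, trial-count weights)")
  print(run$rate_model)
  section("Baseline comparison (one-sided Wilcoxon vs overall -9 rate)")
  print(transform(run$baseline, p = signif(p, 3)), row.names = FALSE)
  section("Reaction-time mixed model (1/RT)")
  print(run$rt_model)
  section("Post-stimulus occupancy (detected vs undetected)")
  print(run$poststim)
  section("Time-resolved occupancy")
  print(run$time_resolved)
  section("Ratings correlations (Spearman, FDR)")
  if (is.null(run$ratings_cor)) cat("[absent]\n") else
    print(transform(run$ratings_cor, rho = round(rho, 3),
                    p = signif(p, 3), p_fdr = signif(p_fdr, 3)),
          row.names = FALSE)
  section("Surrogate control")
  if (is.null(run$surrogate)) cat("[absent]\n") else print(run$surrogate)
  invisible(run)
}
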