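# Derive reproducible child seeds (< 2^31) from one master seed.
child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# One task block with behavior-state coupling: the Markov chain and the
# observer are stepped jointly so a detection can bias the next
# post_detection_window volumes' transitions toward the favorable state.
# When post_detection_bias is 0 the chain is independent of behavior and is
# sampled in one pass.
sim_task_block <- function(config, sched_block, volume_db, alpha_offset,
                           seed) {
  set.seed(seed)
  tr <- config$tr
  n_vol <- config$block_volumes
  k <- config$n_states
  trans <- config$transition_matrix
  fav <- config$favorable_state
  bias <- config$post_detection_bias
  sched <- sched_block[order(sched_block$onset), , drop = FALSE]
  onset_vol <- floor(sched$onset / tr) + 1L
  if (any(onset_vol > n_vol))
    stop(sprintf("trial %d of block %d: onset %.1f s beyond run duration",
                 sched$trial[which.max(onset_vol)], sched$block[1L],
                 max(sched$onset)))

  n_tr <- nrow(sched)
  detected <- logical(n_tr); rt <- rep(NA_real_, n_tr); prev <- rep(NA, n_tr)
  state_at <- integer(n_tr)

  draw_trial <- function(r, s_now, prev_det) {
    if (sched$snr[r] == "catch") {
      p <- config$psychometric$guess
    } else {
      p <- psychometric_p(as.numeric(sched$snr[r]), volume_db,
                          config$psychometric, alpha_offset)
      if (s_now == fav && sched$snr[r] == "-9") p <- p + config$state_boost
      if (isTRUE(prev_det)) p <- p + config$hysteresis
      p <- min(max(p, 0), 1)
    }
    stats::runif(1) < p
  }

  if (bias <= 0) {
    u <- stats::runif(n_vol)
    s <- cpp_markov_sample(stationary_distribution(trans), trans, u)
    prev_det <- NA
    for (r in seq_len(n_tr)) {
      state_at[r] <- s[onset_vol[r]]
      detected[r] <- draw_trial(r, state_at[r], prev_det)
      if (detected[r]) rt[r] <- rt_draw(1, sched$snr[r], config)
      prev[r] <- prev_det
      prev_det <- detected[r]
    }
  } else {
    bias_vols <- as.integer(round(config$post_detection_window / tr))
    s <- integer(n_vol)
    s[1L] <- sample.int(k, 1L, prob = stationary_distribution(trans))
    bias_left <- 0L
    prev_det <- NA
    next_trial <- 1L
    for (t in seq_len(n_vol)) {
      if (t > 1L) {
        row <- trans[s[t - 1L], ]
        if (bias_left > 0L) {
          row <- (1 - bias) * row
          row[fav] <- row[fav] + bias
          bias_left <- bias_left - 1L
        }
        s[t] <- sample.int(k, 1L, prob = row)
      }
      while (next_trial <= n_tr && onset_vol[next_trial] == t) {
        r <- next_trial
        state_at[r] <- s[t]
        detected[r] <- draw_trial(r, s[t], prev_det)
        if (detected[r]) {
          rt[r] <- rt_draw(1, sched$snr[r], config)
          bias_left <- bias_vols
        }
        prev[r] <- prev_det
        prev_det <- detected[r]
        next_trial <- next_trial + 1L
      }
    }
  }

  latent <- structure(list(states = as.integer(s),
                           times = (seq_len(n_vol) - 1) * tr,
                           k = k, tr = tr), class = "latent_states")
  trials <- data.frame(block = sched$block, trial = sched$trial,
                       onset = sched$onset, snr = sched$snr,
                       detected = detected, rt = rt,
                       prev_detected = as.logical(prev),
                       state_at_onset = state_at, stringsAsFactors = FALSE)
  list(latent = latent, trials = trials)
}

#' Simulate one subject's full session
#'
#' Generates a subject-specific detection threshold, a calibrated stimulus
#' volume (the staircase target plus residual calibration error), a rest run
#' (latent chain and, optionally, ROI signals), the task blocks with the
#' observer coupled to the latent chain (detections bias subsequent
#' transitions toward the favorable state when `post_detection_bias > 0`),
#' and block-level subjective ratings.
#'
#' @param config a [generator_config()].
#' @param seed integer seed for this subject.
#' @param subject_id subject label.
#' @param bold generate ROI signal matrices (default `TRUE`; `FALSE` keeps
#'   only latent states, schedules and behavior — useful for behavioral
#'   simulations at scale).
#' @return Object of class `subject_sim`: `subject_id`, `alpha_offset`,
#'   `volume_db`, `rest` (list: `latent`, `ts`), `task` (per block: `latent`,
#'   `ts`, schedule), `trials` (trial_table), `ratings`.
#' @export
simulate_subject <- function(config, seed = NULL, subject_id = "s01",
                             bold = TRUE) {
  stopifnot(inherits(config, "phasestates_config"))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  seeds <- child_seeds(seed, 6L + 2L * config$n_blocks)

  set.seed(seeds[1L])
  alpha_offset <- stats::rnorm(1, sd = config$subject_sd)
  # staircase target: 50% at SNR -9 => volume = alpha + offset + 9, plus
  # residual calibration error
  volume_db <- config$psychometric$alpha + alpha_offset + 9 +
    stats::rnorm(1, sd = config$calibration_sd)

  rest_latent <- make_latent_states(config, config$rest_volumes,
                                    seed = seeds[2L])
  rest_ts <- if (bold) make_bold(rest_latent, config, seed = seeds[3L],
                                 subject_id = subject_id,
                                 run_label = "rest") else NULL

  schedule <- make_schedule(config, seed = seeds[4L])
  task <- vector("list", config$n_blocks)
  trials <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    sb <- sim_task_block(config, schedule[schedule$block == b, , drop = FALSE],
                         volume_db, alpha_offset, seed = seeds[4L + 2L * b])
    ts_b <- if (bold) make_bold(sb$latent, config,
                                seed = seeds[5L + 2L * b],
                                subject_id = subject_id,
                                run_label = "task") else NULL
    task[[b]] <- list(latent = sb$latent, ts = ts_b,
                      schedule = schedule[schedule$block == b, , drop = FALSE])
    trials[[b]] <- sb$trials
  }
  trials <- do.call(rbind, trials)
  trials <- cbind(subject = subject_id, trials, stringsAsFactors = FALSE)
  class(trials) <- c("trial_table", "data.frame")

  occ <- vapply(task, function(tb)
    mean(tb$latent$states == config$tired_state), 1)
  ratings <- make_ratings(
    data.frame(subject = subject_id, block = seq_len(config$n_blocks)),
    occ, config, seed = seeds[5L])

  structure(
    list(subject_id = subject_id, alpha_offset = alpha_offset,
         volume_db = volume_db, rest = list(latent = rest_latent,
                                            ts = rest_ts),
         task = task, trials = trials, ratings = ratings, seed = seed),
    class = "subject_sim")
}

#' @export
print.subject_sim <- function(x, ...) {
  cat(sprintf("<subject_sim> %s: volume %.2f dB, %d trials, %d blocks\n",
              x$subject_id, x$volume_db, nrow(x$trials), length(x$task)))
  invisible(x)
}

#' Simulate a multi-subject study
#'
#' Runs [simulate_subject()] for `config$n_subjects` subjects with child
#' seeds derived from one master seed, and pools trial tables and ratings.
#'
#' @param config a [generator_config()].
#' @param seed master seed (defaults to `config$rng_seed`).
#' @param bold generate ROI signal matrices (see [simulate_subject()]).
#' @return Object of class `study_sim`: `subjects` (list of `subject_sim`),
#'   `trials` (pooled trial_table), `ratings` (pooled), `config`, `seed`.
#' @export
simulate_study <- function(config, seed = config$rng_seed, bold = TRUE) {
  stopifnot(inherits(config, "phasestates_config"))
  if (is.null(seed)) stop("supply 'seed' (or set rng_seed in the config)")
  seeds <- child_seeds(seed, config$n_subjects)
  subjects <- lapply(seq_len(config$n_subjects), function(i)
    simulate_subject(config, seed = seeds[i],
                     subject_id = sprintf("s%02d", i), bold = bold))
  trials <- do.call(rbind, lapply(subjects, `[[`, "trials"))
  class(trials) <- c("trial_table", "data.frame")
  structure(
    list(subjects = subjects, trials = trials,
         ratings = do.call(rbind, lapply(subjects, `[[`, "ratings")),
         config = config, seed = seed),
    class = "study_sim")
}

#' @export
print.study_sim <- function(x, ...) {
  cat(sprintf("<study_sim> %d subjects, %d trials (seed %d)\n",
              length(x$subjects), nrow(x$trials), x$seed))
  invisible(x)
}

#' Long-format state table from simulated or labeled runs
#'
#' Collects per-volume state labels into one data.frame keyed by subject and
#' block, the join format used by the behavioral analyses. Accepts a
#' `study_sim` (latent truth), a single `subject_sim`, or a list of labeled
#' `state_sequence` objects arranged as `x[[subject]][[block]]`.
#'
#' @param x the object to flatten.
#' @param use `"latent"` (planted truth) for simulations; ignored for
#'   `state_sequence` input.
#' @return data.frame `subject`, `block`, `volume` (1-based), `time_s`,
#'   `label`; attribute `"tr"`.
#' @export
state_table <- function(x, use = "latent") {
  one_block <- function(subject, block, labels, tr) {
    data.frame(subject = subject, block = block,
               volume = seq_along(labels),
               time_s = (seq_along(labels) - 1) * tr,
               label = as.integer(labels), stringsAsFactors = FALSE)
  }
  rows <- list()
  if (inherits(x, "study_sim")) x <- x$subjects
  if (inherits(x, "subject_sim")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "subject_sim"))) {
    for (s in x)
      for (b in seq_along(s$task))
        rows[[length(rows) + 1L]] <-
          one_block(s$subject_id, b, s$task[[b]]$latent$states,
                    s$task[[b]]$latent$tr)
    tr <- x[[1L]]$task[[1L]]$latent$tr
  } else if (is.list(x)) {
    subj_names <- names(x)
    if (is.null(subj_names)) subj_names <- sprintf("s%02d", seq_along(x))
    for (i in seq_along(x)) {
      blocks <- x[[i]]
      if (inherits(blocks, "state_sequence")) blocks <- list(blocks)
      for (b in seq_along(blocks))
        rows[[length(rows) + 1L]] <-
          one_block(subj_names[i], b, blocks[[b]]$labels, blocks[[b]]$tr)
    }
    tr <- if (inherits(x[[1L]], "state_sequence")) x[[1L]]$tr
          else x[[1L]][[1L]]$tr
  } else stop("unsupported input for state_table()")
  out <- do.call(rbind, rows)
  attr(out, "tr") <- tr
  out
}
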