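# Deterministic per-ROI jitter pattern used by the default state templates:
# a fixed quasi-random sequence in [-1, 1] (golden-angle stride), so default
# configs are identical across machines without consuming RNG state.
roi_jitter <- function(p) sin(seq_len(p) * 2.399963229728653)

#' Default per-state ROI phase offsets
#'
#' Builds the planted phase geometry behind the default coherence templates.
#' ROIs are split into 6 modules; each state assigns a phase to every module
#' plus a state-specific amount of fixed per-ROI jitter. State 1 (antiphase
#' module blocks, low jitter) has the strongest absolute coherence and plays
#' the role of the detection-favorable, conscious-state-like pattern; state 4
#' (spread phases) is the designated tired-state pattern; state 5 distributes
#' phases around the circle, giving the weakest coherence.
#'
#' @param p number of ROIs (default 42).
#' @param k number of states; only the default 5 is pre-defined.
#' @return k x p matrix of phase offsets (radians).
#' @export
default_phase_offsets <- function(p = 42L, k = 5L) {
  if (k != 5L) stop("default phase offsets are defined for k = 5; supply ",
                    "'state_phase_offsets' for other state counts")
  modules <- ((seq_len(p) - 1L) %/% ceiling(p / 6)) + 1L
  modules[modules > 6L] <- 6L
  z <- roi_jitter(p)
  module_phase <- rbind(
    c(0, pi, 0, pi, 0, pi),                     # s1: strong +/- block structure
    c(0, 0, 2 * pi / 3, 2 * pi / 3, 4 * pi / 3, 4 * pi / 3),  # s2: 3 modules
    rep(0, 6),                                  # s3: globally positive
    c(0, pi / 2, pi, 3 * pi / 2, 0, pi / 2),    # s4: mixed ("tired") profile
    c(0, 0, 0, pi, pi, pi))                     # s5: coarse split, weak
  jit <- c(0.25, 0.35, 0.9, 0.6, 0.8)
  off <- matrix(0, k, p)
  for (s in seq_len(k)) off[s, ] <- module_phase[s, modules] + jit[s] * z
  off
}

# Coherence template implied by a phase-offset vector: T[i, j] = cos(psi_i -
# psi_j), symmetric with unit diagonal by construction.
template_from_offsets <- function(psi) {
  outer(psi, psi, function(a, b) cos(a - b))
}

# Fit phase offsets realizing a coherence template: circular embedding from
# the top-2 eigenvectors of T (if T = cos(psi_i - psi_j) exactly, T = u u' +
# v v' with u = cos psi, v = sin psi), refined by least squares on the upper
# triangle. Returns list(psi, error = max |cos(psi_i - psi_j) - T_ij|).
fit_phase_offsets <- function(template) {
  e <- eigen(template, symmetric = TRUE)
  xy <- e$vectors[, 1:2] %*% diag(sqrt(pmax(e$values[1:2], 1e-12)))
  psi <- atan2(xy[, 2L], xy[, 1L])
  p <- length(psi)
  ut <- upper.tri(template)
  obj <- function(ps) sum((cos(outer(ps, ps, "-"))[ut] - template[ut])^2)
  opt <- stats::optim(psi, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  psi <- opt$par
  err <- max(abs(cos(outer(psi, psi, "-"))[ut] - template[ut]))
  list(psi = psi, error = err)
}

#' Synthetic-study generator configuration
#'
#' Collects every constant of the emulated study: a 42-ROI parcellation
#' sampled at TR = 1 s, a 600-volume rest run, 5 recurrent coherence states
#' switching under a Markov chain, a 6-block auditory detection task (10
#' trials per SNR in \{-7, -9, -11\} dB plus 3 catch trials per block, onsets
#' every 14 +/- 1 s), a logistic observer calibrated to 50% detection at
#' SNR -9 whose threshold detection probability is raised by `state_boost`
#' when the favorable state is active at stimulus time and by `hysteresis`
#' after a detected trial, and a post-detection transition bias toward the
#' favorable state.
#'
#' States are realized as per-ROI phase offsets: ROI i's signal in state s is
#' `cos(carrier_phase(t) + psi[s, i]) + noise`, so the per-volume coherence of
#' pair (i, j) approximates `cos(psi[s, i] - psi[s, j])`, the template entry.
#' If `state_templates` are supplied directly, offsets realizing them are
#' fitted (circular embedding + least squares); the per-state approximation
#' error is stored in `$template_error` and an error above `template_tol`
#' aborts rather than silently degrading the planted structure.
#'
#' @param n_subjects subjects in the study (default 25).
#' @param n_rois ROIs P (default 42; coherence dimension P(P-1)/2 = 861).
#' @param tr repetition time, seconds.
#' @param rest_volumes rest-run length in volumes (default 600).
#' @param n_states planted state count K (default 5).
#' @param state_phase_offsets optional K x P matrix of phase offsets defining
#'   the states (default [default_phase_offsets()]).
#' @param state_templates optional list/array of K symmetric unit-diagonal
#'   P x P coherence templates; mutually exclusive with
#'   `state_phase_offsets`.
#' @param template_tol maximum tolerated template approximation error.
#' @param transition_matrix K x K row-stochastic matrix; default: stay
#'   probability `1 - tr / dwell_scale`, remainder spread uniformly.
#' @param dwell_scale mean state dwell time, seconds (default 10).
#' @param carrier_band frequency interval (Hz) of the shared slow carrier
#'   oscillation (default c(0.01, 0.1)).
#' @param noise_sd additive Gaussian noise SD relative to the unit-amplitude
#'   oscillation (reference level 0.25).
#' @param psychometric list with `alpha` (threshold location, dB), `beta`
#'   (slope, 1/dB), `lapse`, `guess` (catch false-alarm rate).
#' @param state_boost additive detection-probability boost at SNR -9 when the
#'   favorable state is active (default 0.12, the size of the published
#'   Pattern-1 advantage).
#' @param hysteresis additive boost after a detected previous trial.
#' @param favorable_state,tired_state planted indices of the
#'   detection-favorable and tiredness-associated states.
#' @param post_detection_bias mixing weight toward the favorable state applied
#'   to the transition row for `post_detection_window` volumes after a
#'   detection (0 disables the feedback).
#' @param post_detection_window seconds of biased transitions after detection.
#' @param subject_sd between-subject SD of the detection threshold (dB).
#' @param calibration_sd SD of the residual volume-calibration error (dB).
#' @param n_blocks,trials_per_snr,n_catch,snr_levels task design constants.
#' @param isi_range inter-onset interval range, seconds.
#' @param first_onset_range range of the first onset within a block, seconds.
#' @param block_volumes task-block run length in volumes (8 min at TR 1 s).
#' @param stair_start,stair_step staircase starting volume (dB above `alpha`)
#'   and step size (dB).
#' @param rt_mean named mean RT (s) per SNR level; RTs are lognormal with
#'   `rt_sdlog` log-scale SD.
#' @param rt_sdlog lognormal log-scale SD of RTs.
#' @param rating_noise SD of the latent noise in the tiredness rating map.
#' @param rng_seed optional default master seed recorded in the config.
#' @return Object of class `phasestates_config` (a validated list; also
#'   carries `$phase_offsets`, `$state_templates`, `$template_error`).
#' @examples
#' cfg <- generator_config(n_subjects = 2, rest_volumes = 60)
#' cfg$n_states
#' @export
generator_config <- function(
    n_subjects = 25L, n_rois = 42L, tr = 1, rest_volumes = 600L,
    n_states = 5L, state_phase_offsets = NULL, state_templates = NULL,
    template_tol = 0.05, transition_matrix = NULL, dwell_scale = 10,
    carrier_band = c(0.01, 0.1), noise_sd = 0.25,
    psychometric = list(alpha = 0, beta = 0.8, lapse = 0.02, guess = 0.002),
    state_boost = 0.12, hysteresis = 0.08,
    favorable_state = 1L, tired_state = 4L,
    post_detection_bias = 0.25, post_detection_window = 9,
    subject_sd = 1, calibration_sd = 0.5,
    n_blocks = 6L, trials_per_snr = 10L, n_catch = 3L,
    snr_levels = c(-7, -9, -11), isi_range = c(13, 15),
    first_onset_range = c(10, 12), block_volumes = 480L,
    stair_start = 15, stair_step = 1,
    rt_mean = c("-7" = 1.02, "-9" = 1.10, "-11" = 1.20), rt_sdlog = 0.25,
    rating_noise = 0.7, rng_seed = NULL) {

  k <- as.integer(n_states)
  p <- as.integer(n_rois)

  if (!is.null(state_templates) && !is.null(state_phase_offsets))
    stop("supply 'state_templates' or 'state_phase_offsets', not both")
  template_error <- rep(0, k)
  if (!is.null(state_templates)) {
    if (is.array(state_templates) && length(dim(state_templates)) == 3L)
      state_templates <- lapply(seq_len(dim(state_templates)[3L]),
                                function(i) state_templates[, , i])
    if (length(state_templates) != k)
      stop("need ", k, " state templates, got ", length(state_templates))
    off <- matrix(0, k, p)
    for (s in seq_len(k)) {
      tmpl <- state_templates[[s]]
      if (!isTRUE(all.equal(tmpl, t(tmpl))) ||
          any(abs(diag(tmpl) - 1) > 1e-9) || any(abs(tmpl) > 1 + 1e-9))
        stop("template ", s, " must be symmetric with unit diagonal and ",
             "entries in [-1, 1]")
      ft <- fit_phase_offsets(tmpl)
      template_error[s] <- ft$error
      off[s, ] <- ft$psi
      message(sprintf("state %d: template approximation error %.4f",
                      s, ft$error))
    }
    if (max(template_error) > template_tol)
      stop("template approximation error ", signif(max(template_error), 3),
           " exceeds template_tol = ", template_tol,
           "; the template is not realizable as a circular phase-offset ",
           "pattern at this tolerance")
    state_phase_offsets <- off
  }
  if (is.null(state_phase_offsets))
    state_phase_offsets <- default_phase_offsets(p, k)
  if (!all(dim(state_phase_offsets) == c(k, p)))
    stop("'state_phase_offsets' must be a ", k, " x ", p, " matrix")
  templates <- lapply(seq_len(k), function(s)
    template_from_offsets(state_phase_offsets[s, ]))

  if (is.null(transition_matrix)) {
    stay <- max(0, 1 - tr / dwell_scale)
    transition_matrix <- matrix((1 - stay) / (k - 1), k, k)
    diag(transition_matrix) <- stay
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(k, k)) ||
      any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12))
    stop("'transition_matrix' must be ", k, " x ", k,
         " row-stochastic (rows summing to 1, entries >= 0)")

  ps <- psychometric
  for (f in c("alpha", "beta", "lapse", "guess"))
    if (is.null(ps[[f]])) stop("psychometric parameter '", f, "' missing")
  if (ps$lapse < 0 || ps$lapse > 0.05 || ps$guess < 0 || ps$guess > 0.05)
    stop("'lapse' and 'guess' must lie in [0, 0.05]")
  if (state_boost < 0 || state_boost > 0.5 ||
      hysteresis < 0 || hysteresis > 0.5)
    stop("'state_boost' and 'hysteresis' must lie in [0, 0.5]")
  if (!favorable_state %in% seq_len(k) || !tired_state %in% seq_len(k))
    stop("'favorable_state' and 'tired_state' must index a planted state")
  stopifnot(length(carrier_band) == 2L, carrier_band[1] > 0,
            carrier_band[2] >= carrier_band[1],
            isi_range[1] <= isi_range[2], noise_sd >= 0)

  structure(
    list(n_subjects = as.integer(n_subjects), n_rois = p, tr = tr,
         rest_volumes = as.integer(rest_volumes), n_states = k,
         phase_offsets = state_phase_offsets, state_templates = templates,
         template_error = template_error, template_tol = template_tol,
         transition_matrix = transition_matrix, dwell_scale = dwell_scale,
         carrier_band = carrier_band, noise_sd = noise_sd,
         psychometric = ps[c("alpha", "beta", "lapse", "guess")],
         state_boost = state_boost, hysteresis = hysteresis,
         favorable_state = as.integer(favorable_state),
         tired_state = as.integer(tired_state),
         post_detection_bias = post_detection_bias,
         post_detection_window = post_detection_window,
         subject_sd = subject_sd, calibration_sd = calibration_sd,
         n_blocks = as.integer(n_blocks),
         trials_per_snr = as.integer(trials_per_snr),
         n_catch = as.integer(n_catch), snr_levels = snr_levels,
         isi_range = isi_range, first_onset_range = first_onset_range,
         block_volumes = as.integer(block_volumes),
         stair_start = stair_start, stair_step = stair_step,
         rt_mean = rt_mean, rt_sdlog = rt_sdlog,
         rating_noise = rating_noise, rng_seed = rng_seed),
    class = "phasestates_config")
}

#' @export
print.phasestates_config <- function(x, ...) {
  cat(sprintf("<phasestates_config> %d subjects, %d ROIs, TR %g s\n",
              x$n_subjects, x$n_rois, x$tr))
  cat(sprintf("  %d planted states (favorable %d, tired %d), dwell ~%g s, noise_sd %g\n",
              x$n_states, x$favorable_state, x$tired_state, x$dwell_scale,
              x$noise_sd))
  cat(sprintf("  task: %d blocks x (%d per SNR {%s} + %d catch), ISI %g-%g s\n",
              x$n_blocks, x$trials_per_snr,
              paste(x$snr_levels, collapse = ", "), x$n_catch,
              x$isi_range[1], x$isi_range[2]))
  invisible(x)
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
stationary_distribution <- function(trans) {
  e <- eigen(t(trans))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Sample the latent state chain
#'
#' Draws a Markov-chain state sequence of the planted coherence states; the
#' initial state comes from the chain's stationary distribution.
#'
#' @param config a [generator_config()].
#' @param n_volumes number of volumes to sample.
#' @param seed integer seed.
#' @return Object of class `latent_states`: `states` (integers in
#'   1..n_states), `times` (seconds), `k`, `tr`.
#' @export
make_latent_states <- function(config, n_volumes, seed = NULL) {
  stopifnot(inherits(config, "phasestates_config"))
  n_volumes <- as.integer(n_volumes)
  if (n_volumes < 1L) stop("'n_volumes' must be >= 1")
  trans <- config$transition_matrix
  if (any(abs(rowSums(trans) - 1) > 1e-12) || any(trans < 0))
    stop("transition matrix is not row-stochastic")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n_volumes)
  s <- cpp_markov_sample(stationary_distribution(trans), trans, u)
  structure(list(states = as.integer(s),
                 times = (seq_len(n_volumes) - 1) * config$tr,
                 k = config$n_states, tr = config$tr),
            class = "latent_states")
}

#' @export
print.latent_states <- function(x, ...) {
  cat(sprintf("<latent_states> %d volumes, %d states; occupancy: %s\n",
              length(x$states), x$k,
              paste(round(tabulate(x$states, x$k) / length(x$states), 3),
                    collapse = " ")))
  invisible(x)
}

#' Generate ROI signals from a latent state sequence
#'
#' ROI i's signal at volume t is `cos(phi(t) + psi[s_t, i]) + noise`, where
#' the shared carrier phase `phi` advances at a frequency drawn uniformly from
#' `carrier_band` and `psi` holds the per-state ROI phase offsets. With zero
#' noise the phase difference of a pair within a state equals the planted
#' offset difference, so the downstream coherence reproduces the active
#' state's template.
#'
#' @param latent a [make_latent_states()] sequence.
#' @param config the [generator_config()] that produced it.
#' @param seed integer seed (carrier frequency and noise).
#' @param subject_id,run_label identifiers for the output container.
#' @return A [roi_timeseries()] with the latent truth attached as attribute
#'   `"latent"`.
#' @export
make_bold <- function(latent, config, seed = NULL, subject_id = "s01",
                      run_label = "rest") {
  stopifnot(inherits(latent, "latent_states"),
            inherits(config, "phasestates_config"))
  if (max(latent$states) > config$n_states)
    stop("latent states exceed the configured state count")
  if (!is.null(seed)) set.seed(seed)
  f <- stats::runif(1, config$carrier_band[1], config$carrier_band[2])
  # snap the carrier to the Fourier grid of the run (integer cycle count):
  # a non-grid frequency leaks spectrally and corrupts the analytic-signal
  # phase at the run edges, degrading the planted coherence structure
  dur <- length(latent$times) * config$tr
  f <- max(1, round(f * dur)) / dur
  phi <- 2 * pi * f * latent$times
  psi <- config$phase_offsets[latent$states, , drop = FALSE]
  # phase-continuous switching: pairwise coherence is invariant to a common
  # rotation of a state's offsets, so rotate each new segment to minimize the
  # signal discontinuity at the switch (less broadband transient energy, less
  # analytic-phase smearing around transitions)
  switch_at <- which(diff(latent$states) != 0L) + 1L
  rot <- 0
  bounds <- c(switch_at, length(latent$states) + 1L)
  for (b in seq_along(switch_at)) {
    t0 <- switch_at[b]
    delta <- Arg(sum(exp(1i * ((psi[t0 - 1L, ] + rot) - psi[t0, ]))))
    rot <- delta
    psi[t0:(bounds[b + 1L] - 1L), ] <-
      psi[t0:(bounds[b + 1L] - 1L), , drop = FALSE] + rot
  }
  x <- cos(phi + psi)
  if (config$noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), sd = config$noise_sd),
                    nrow(x), ncol(x))
  out <- roi_timeseries(x, tr = config$tr, subject_id = subject_id,
                        run_label = run_label)
  attr(out, "latent") <- latent
  attr(out, "carrier_freq") <- f
  out
}

#' Generate a randomized task schedule
#'
#' Six blocks of 33 trials (10 per SNR level plus 3 catch trials, order
#' shuffled within block), with the first onset drawn from
#' `first_onset_range` and successive onsets separated by a uniform
#' inter-stimulus interval (14 +/- 1 s by default).
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return A data.frame with columns `block`, `trial`, `onset` (seconds,
#'   within block) and `snr` (character: `"-7"`, `"-9"`, `"-11"` or
#'   `"catch"`).
#' @export
make_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "phasestates_config"))
  if (!is.null(seed)) set.seed(seed)
  labels <- c(rep(as.character(config$snr_levels),
                  each = config$trials_per_snr),
              rep("catch", config$n_catch))
  n_trial <- length(labels)
  out <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    ord <- sample(labels)
    gaps <- stats::runif(n_trial - 1L, config$isi_range[1],
                         config$isi_range[2])
    onset <- cumsum(c(stats::runif(1, config$first_onset_range[1],
                                   config$first_onset_range[2]), gaps))
    out[[b]] <- data.frame(block = b, trial = seq_len(n_trial),
                           onset = onset, snr = ord,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Core psychometric function: lapse/guess-adjusted logistic of the effective
# level (snr + volume) relative to the threshold location alpha.
psychometric_p <- function(snr_db, volume_db, ps, alpha_offset = 0) {
  ps$guess + (1 - ps$guess - ps$lapse) *
    stats::plogis(ps$beta * (snr_db + volume_db - (ps$alpha + alpha_offset)))
}

#' Observer detection probability
#'
#' The synthetic observer's probability of reporting a stimulus: the
#' lapse/guess-adjusted logistic of the effective level (SNR + volume
#' relative to the threshold location), plus the favorable-state boost (at
#' threshold SNR -9 only) and the hysteresis boost, clipped to \[0, 1\].
#'
#' @param snr_db stimulus SNR in dB.
#' @param volume_db calibrated stimulus volume in dB.
#' @param config a [generator_config()].
#' @param favorable is the favorable state active at stimulus time?
#' @param prev_detected was the previous trial detected?
#' @param alpha_offset subject-specific threshold shift, dB.
#' @return Detection probability.
#' @examples
#' cfg <- generator_config()
#' detection_probability(-9, 9, cfg)
#' @export
detection_probability <- function(snr_db, volume_db, config,
                                  favorable = FALSE, prev_detected = FALSE,
                                  alpha_offset = 0) {
  stopifnot(inherits(config, "phasestates_config"))
  p <- psychometric_p(snr_db, volume_db, config$psychometric, alpha_offset)
  p <- p + config$state_boost * (favorable & snr_db == -9) +
    config$hysteresis * prev_detected
  pmin(pmax(p, 0), 1)
}

rt_draw <- function(n, snr_chr, config) {
  m <- config$rt_mean[snr_chr]
  m[is.na(m)] <- config$rt_mean["-9"]  # catch false alarms: threshold-like RT
  stats::rlnorm(n, meanlog = log(m) - config$rt_sdlog^2 / 2,
                sdlog = config$rt_sdlog)
}

#' Simulate observer responses on a fixed latent state sequence
#'
#' Applies the logistic observer to a schedule: detection probability is the
#' catch false-alarm rate for catch trials, otherwise the lapse-adjusted
#' logistic of the effective level, plus `state_boost` when the favorable
#' state is active at the onset volume and the trial is at threshold
#' (SNR -9), plus `hysteresis` when the previous trial in the block was
#' detected, clipped to \[0, 1\]. Detected trials get a lognormal RT whose
#' location slows with decreasing SNR. The state "at stimulus time" is the
#' state of the volume whose acquisition interval contains the onset.
#'
#' @param schedule a [make_schedule()] data.frame (or a subset of blocks).
#' @param latent a list of [make_latent_states()] sequences, one per block
#'   (a single `latent_states` object is accepted for a one-block schedule).
#' @param config the [generator_config()].
#' @param volume_db stimulus volume (dB) as calibrated by the staircase.
#' @param seed integer seed.
#' @param subject_id subject label; `alpha_offset` shifts this subject's
#'   threshold (dB).
#' @param alpha_offset subject-specific threshold shift, dB.
#' @return A `trial_table` data.frame: `subject`, `block`, `trial`, `onset`,
#'   `snr`, `detected`, `rt` (NA unless detected), `prev_detected` (NA for
#'   each block's first trial), `state_at_onset` (latent truth).
#' @export
simulate_observer <- function(schedule, latent, config, volume_db,
                              seed = NULL, subject_id = "s01",
                              alpha_offset = 0) {
  stopifnot(inherits(config, "phasestates_config"))
  if (inherits(latent, "latent_states")) latent <- list(latent)
  blocks <- sort(unique(schedule$block))
  if (length(latent) < length(blocks))
    stop("'latent' must provide one state sequence per block (",
         length(blocks), " needed)")
  if (!is.null(seed)) set.seed(seed)
  sched <- schedule[order(schedule$block, schedule$onset), , drop = FALSE]
  n <- nrow(sched)
  detected <- logical(n); rt <- rep(NA_real_, n)
  prev <- rep(NA, n); state <- integer(n)
  for (bi in seq_along(blocks)) {
    rows <- which(sched$block == blocks[bi])
    lat <- latent[[bi]]
    prev_det <- NA
    for (r in rows) {
      v <- floor(sched$onset[r] / lat$tr) + 1L
      if (v > length(lat$states))
        stop(sprintf(
          "trial %d of block %d: onset %.1f s beyond run duration (%d volumes)",
          sched$trial[r], sched$block[r], sched$onset[r], length(lat$states)))
      state[r] <- lat$states[v]
      if (sched$snr[r] == "catch") {
        p <- config$psychometric$guess
      } else {
        p <- psychometric_p(as.numeric(sched$snr[r]), volume_db,
                            config$psychometric, alpha_offset)
        if (state[r] == config$favorable_state && sched$snr[r] == "-9")
          p <- p + config$state_boost
        if (isTRUE(prev_det)) p <- p + config$hysteresis
        p <- min(max(p, 0), 1)
      }
      detected[r] <- stats::runif(1) < p
      if (detected[r]) rt[r] <- rt_draw(1, sched$snr[r], config)
      prev[r] <- prev_det
      prev_det <- detected[r]
    }
  }
  out <- data.frame(subject = subject_id, block = sched$block,
                    trial = sched$trial, onset = sched$onset,
                    snr = sched$snr, detected = detected, rt = rt,
                    prev_detected = as.logical(prev),
                    state_at_onset = state, stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Simulate the volume-calibration staircase
#'
#' One-up-one-down adaptive staircase on the logistic observer at SNR -9: a
#' detection lowers the stimulus volume by one step, a miss raises it, which
#' converges on the 50% point of the psychometric function. The converged
#' volume is the mean level over reversals after discarding the first 20% of
#' reversals.
#'
#' @param config a [generator_config()].
#' @param n_trials staircase length (>= 50).
#' @param seed integer seed.
#' @param start,step starting volume and step size (dB); default
#'   `alpha + stair_start` and `stair_step`.
#' @param alpha_offset subject-specific threshold shift, dB.
#' @return Object of class `staircase_fit`: `volume_db` (converged level),
#'   `levels` (per-trial volumes), `reversals` (trial indices),
#'   `n_reversals`.
#' @export
simulate_staircase <- function(config, n_trials = 200L, seed = NULL,
                               start = NULL, step = NULL, alpha_offset = 0) {
  stopifnot(inherits(config, "phasestates_config"))
  n_trials <- as.integer(n_trials)
  if (n_trials < 50L) stop("'n_trials' must be >= 50")
  if (is.null(start)) start <- config$psychometric$alpha + config$stair_start
  if (is.null(step)) step <- config$stair_step
  if (!is.null(seed)) set.seed(seed)
  if (step == 0) {
    return(structure(list(volume_db = start, levels = rep(start, n_trials),
                          reversals = integer(0), n_reversals = 0L),
                     class = "staircase_fit"))
  }
  levels <- numeric(n_trials)
  lvl <- start
  dir_prev <- 0L
  reversals <- integer(0)
  for (i in seq_len(n_trials)) {
    levels[i] <- lvl
    p <- psychometric_p(-9, lvl, config$psychometric, alpha_offset)
    det <- stats::runif(1) < p
    dir <- if (det) -1L else 1L
    if (dir_prev != 0L && dir != dir_prev) reversals <- c(reversals, i)
    dir_prev <- dir
    lvl <- lvl + dir * step
  }
  if (length(reversals) == 0L)
    stop("no reversal observed; increase 'n_trials'")
  keep <- reversals[-seq_len(floor(0.2 * length(reversals)))]
  if (length(keep) == 0L) keep <- reversals
  structure(list(volume_db = mean(levels[keep]), levels = levels,
                 reversals = reversals, n_reversals = length(reversals)),
            class = "staircase_fit")
}

#' @export
print.staircase_fit <- function(x, ...) {
  cat(sprintf("<staircase_fit> converged volume %.2f dB (%d reversals over %d trials)\n",
              x$volume_db, x$n_reversals, length(x$levels)))
  invisible(x)
}

#' Circular-shift surrogate of an ROI run
#'
#' Rotates each ROI's series independently by a uniform random offset
#' (wrap-around), preserving every column's own values and circular
#' autocorrelation while destroying the temporal alignment between ROIs.
#' This is the null model for the pattern-dictionary control analysis.
#'
#' @param ts a [roi_timeseries()].
#' @param seed integer seed.
#' @param shifts optional integer vector of per-ROI offsets in 0..T-1 (a
#'   testing hook; default: uniform random in 1..T-1 per ROI).
#' @return A [roi_timeseries()] with `run_label = "surrogate"`.
#' @export
circular_shift_surrogate <- function(ts, seed = NULL, shifts = NULL) {
  stopifnot(inherits(ts, "roi_ts"))
  n <- nrow(ts$data); p <- ncol(ts$data)
  if (n < 2L) stop("need at least 2 volumes")
  if (is.null(shifts)) {
    if (!is.null(seed)) set.seed(seed)
    shifts <- sample.int(n - 1L, p, replace = TRUE)
  }
  shifts <- as.integer(shifts)
  if (length(shifts) == 1L) shifts <- rep(shifts, p)
  stopifnot(length(shifts) == p, all(shifts >= 0L), all(shifts < n))
  out <- ts$data
  for (j in seq_len(p)) {
    s <- shifts[j]
    if (s > 0L) out[, j] <- ts$data[c((n - s + 1L):n, 1L:(n - s)), j]
  }
  res <- roi_timeseries(out, tr = ts$tr, subject_id = ts$subject_id,
                        run_label = "surrogate", roi_names = ts$roi_names)
  attr(res, "shifts") <- shifts
  res
}

#' Generate block-level subjective ratings
#'
#' Tiredness is a noisy monotone map of the tired-state occupancy in the
#' block: `1 + 6 * occupancy` plus Gaussian noise, rounded and clipped to the
#' 1..7 scale, so blocks with more tired-state volumes are rated more tiring.
#' Success and focus ratings carry no planted structure (noise around the
#' scale midpoint).
#'
#' @param subject_blocks data.frame with columns `subject` and `block`,
#'   one row per rated block, aligned with `occupancy`.
#' @param occupancy tired-state occupancy per block, in \[0, 1\].
#' @param config a [generator_config()] (uses `rating_noise`).
#' @param seed integer seed.
#' @return data.frame `subject`, `block`, `tiredness`, `success`, `focus`
#'   (integers 1..7).
#' @export
make_ratings <- function(subject_blocks, occupancy, config, seed = NULL) {
  stopifnot(inherits(config, "phasestates_config"),
            nrow(subject_blocks) == length(occupancy),
            all(occupancy >= 0 & occupancy <= 1))
  if (!is.null(seed)) set.seed(seed)
  n <- length(occupancy)
  clip7 <- function(x) pmin(pmax(as.integer(round(x)), 1L), 7L)
  tired <- clip7(1 + 6 * occupancy +
                   stats::rnorm(n, sd = config$rating_noise))
  data.frame(subject = subject_blocks$subject, block = subject_blocks$block,
             tiredness = tired,
             success = clip7(4 + stats::rnorm(n, sd = 1.2)),
             focus = clip7(4 + stats::rnorm(n, sd = 1.2)),
             stringsAsFactors = FALSE)
}
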