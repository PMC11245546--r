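test_that("latent chains honor the transition structure", {
  # absorbing chain: identity transitions keep the initial state
  cfg <- toy_config(transition_matrix = diag(2))
  lat <- make_latent_states(cfg, 50, seed = 1)
  expect_identical(length(unique(lat$states)), 1L)
  # law of large numbers: uniform chain visits every state equally
  cfg5 <- generator_config(transition_matrix = matrix(0.2, 5, 5))
  occ <- tabulate(make_latent_states(cfg5, 50000, seed = 2)$states, 5) / 50000
  expect_true(all(abs(occ - 0.2) <= 0.01))
  # boundary: a single volume
  expect_identical(length(make_latent_states(cfg5, 1, seed = 3)$states), 1L)
  expect_error(generator_config(transition_matrix = matrix(1, 5, 5)),
               "row-stochastic")
})

test_that("noiseless signals reproduce the planted templates exactly within a state", {
  # all offsets equal: every pair coheres at +1
  cfg1 <- toy_config(offsets = rbind(rep(0, 6), rep(1, 6)), noise_sd = 0,
                     transition_matrix = diag(2))
  lat <- make_latent_states(cfg1, 80, seed = 4)
  ch <- coherence_series(instantaneous_phase(make_bold(lat, cfg1, seed = 5)))
  expect_lt(max(abs(ch$vectors - 1)), 1e-9)
  # two antiphase groups: within +1, between -1
  cfg2 <- toy_config(noise_sd = 0, transition_matrix = diag(2))
  lat2 <- structure(list(states = rep(2L, 80), times = 0:79, k = 2, tr = 1),
                    class = "latent_states")
  ch2 <- coherence_series(instantaneous_phase(make_bold(lat2, cfg2, seed = 6)))
  tmpl <- vector_from_matrix(cfg2$state_templates[[2]])
  expect_lt(max(abs(sweep(ch2$vectors, 2, tmpl))), 1e-9)
  expect_true(all(abs(abs(tmpl) - 1) < 1e-12))
  # each default-state template is recovered within the documented tolerance
  cfgd <- generator_config(noise_sd = 0)
  for (s in c(1, 4)) {
    latc <- structure(list(states = rep(s, 120L), times = 0:119, k = 5,
                           tr = 1), class = "latent_states")
    chc <- coherence_series(instantaneous_phase(
      make_bold(latc, cfgd, seed = 6 + s)))
    tm <- vector_from_matrix(cfgd$state_templates[[s]])
    expect_lt(max(abs(sweep(chc$vectors, 2, tm))), 0.05)
  }
})

test_that("default synthetic volumes correlate strongly with the active template", {
  # the documented reference run: default config, latent seed 42, signal
  # seed 142 (the noise-level calibration condition)
  cfg <- generator_config()
  lat <- make_latent_states(cfg, cfg$rest_volumes, seed = 42)
  ch <- coherence_series(instantaneous_phase(make_bold(lat, cfg, seed = 142)))
  tmplv <- t(vapply(cfg$state_templates, vector_from_matrix,
                    numeric(choose(42, 2))))
  r <- vapply(seq_len(cfg$rest_volumes), function(t)
    cor(ch$vectors[t, ], tmplv[lat$states[t], ]), 1)
  expect_gt(mean(r), 0.8)
})

test_that("task schedules have the published composition and jitter", {
  cfg <- generator_config()
  for (seed in c(1, 77)) {
    sch <- make_schedule(cfg, seed = seed)
    expect_identical(nrow(sch), 198L)
    comp <- table(sch$block, sch$snr)
    expect_true(all(comp[, c("-7", "-9", "-11")] == 10))
    expect_true(all(comp[, "catch"] == 3))
    gaps <- unlist(lapply(split(sch, sch$block),
                          function(b) diff(sort(b$onset))))
    expect_true(all(gaps >= 13 & gaps <= 15))
  }
  expect_identical(make_schedule(cfg, seed = 9), make_schedule(cfg, seed = 9))
})

test_that("the observer saturates, never false-alarms with zero guess, and boosts at threshold", {
  cfg <- toy_config(psychometric = list(alpha = 0, beta = 50, lapse = 0.02,
                                        guess = 0),
                    state_boost = 0, hysteresis = 0,
                    transition_matrix = diag(2), n_blocks = 1)
  sch <- make_schedule(cfg, seed = 11)
  lat <- list(structure(list(states = rep(1L, 480), times = 0:479, k = 2,
                             tr = 1), class = "latent_states"))
  tt <- simulate_observer(sch, lat, cfg, volume_db = 30, seed = 12)
  # far above threshold: every stimulus detected up to the lapse rate
  expect_gt(mean(tt$detected[tt$snr == "-7"]), 1 - 0.02 - 0.15)
  expect_identical(sum(tt$detected[tt$snr == "catch"]), 0L)
  expect_true(is.na(tt$prev_detected[1]))
  expect_true(all(!is.na(tt$prev_detected[-1])))
  expect_true(all(is.na(tt$rt[!tt$detected])))
  expect_true(all(!is.na(tt$rt[tt$detected])))
  # onsets past the run end are reported with the trial id
  short <- list(structure(list(states = rep(1L, 20), times = 0:19, k = 2,
                               tr = 1), class = "latent_states"))
  expect_error(simulate_observer(sch, short, cfg, volume_db = 30, seed = 1),
               "beyond run duration")
})

test_that("favorable-state trials gain the planted boost at threshold", {
  # alternating-state latent, no hysteresis: SNR -9 detection differs by delta
  cfg <- toy_config(state_boost = 0.15, hysteresis = 0,
                    calibration_sd = 0, subject_sd = 0, n_blocks = 60)
  sch <- make_schedule(cfg, seed = 13)
  lat <- lapply(seq_len(cfg$n_blocks), function(b)
    structure(list(states = rep(c(1L, 2L), 240), times = 0:479, k = 2,
                   tr = 1), class = "latent_states"))
  tt <- simulate_observer(sch, lat, cfg, volume_db = 9, seed = 14)
  t9 <- tt[tt$snr == "-9", ]
  gap <- mean(t9$detected[t9$state_at_onset == 1]) -
    mean(t9$detected[t9$state_at_onset == 2])
  expect_lt(abs(gap - 0.15), 0.08)
  # analytic mixture oracle: the non-favorable rate is the plain logistic
  p0 <- detection_probability(-9, 9, cfg)
  expect_equal(mean(t9$detected[t9$state_at_onset == 2]), p0,
               tolerance = 0.06)
})

test_that("the staircase oscillates around the threshold and converges to 50%", {
  cfg <- generator_config(psychometric = list(alpha = 0, beta = 1e6,
                                              lapse = 0, guess = 0))
  st <- simulate_staircase(cfg, 100, seed = 15, start = 15.5, step = 1)
  burn <- st$levels[30:100]
  expect_true(all(burn >= 8.4 & burn <= 10.6))  # one-step band around alpha+9
  expect_equal(st$volume_db, 9, tolerance = 0.6)
  # logistic observer: converged level sits at the 50% point
  cfgl <- generator_config()
  stl <- simulate_staircase(cfgl, 1000, seed = 16)
  p <- detection_probability(-9, stl$volume_db, cfgl)
  expect_equal(p, 0.5, tolerance = 0.05)
  # degenerate step: level never moves
  st0 <- simulate_staircase(cfgl, 60, seed = 17, step = 0)
  expect_identical(st0$volume_db, cfgl$psychometric$alpha + cfgl$stair_start)
  # a descent that never reverses is reported (lapse-free observer far
  # above threshold detects every trial)
  cfgd <- generator_config(psychometric = list(alpha = 0, beta = 0.8,
                                               lapse = 0, guess = 0))
  expect_error(simulate_staircase(cfgd, 50, seed = 18, start = 500, step = 1),
               "reversal")
})

test_that("circular shifts preserve marginals and autocorrelation, killing cross-ROI alignment", {
  set.seed(19)
  x <- roi_timeseries(matrix(rnorm(600 * 6), 600, 6), tr = 1)
  s <- circular_shift_surrogate(x, seed = 20)
  expect_identical(attr(s, "shifts") >= 1L, rep(TRUE, 6))
  for (j in 1:6)
    expect_identical(sort(s$data[, j]), sort(x$data[, j]))
  # circular autocorrelation identical (FFT periodogram comparison)
  circ_acf <- function(v) Re(stats::fft(Mod(stats::fft(v))^2,
                                        inverse = TRUE)) / length(v)
  for (j in 1:6)
    expect_equal(circ_acf(s$data[, j]), circ_acf(x$data[, j]),
                 tolerance = 1e-10)
  # lag-0 cross correlations center on zero for white noise
  r <- cor(s$data)
  expect_lt(mean(abs(r[upper.tri(r)])), 2 / sqrt(600) + 0.02)
  # forced zero shift reproduces the input
  s0 <- circular_shift_surrogate(x, shifts = rep(0L, 6))
  expect_identical(s0$data, x$data)
})

test_that("tiredness ratings rise monotonically with tired-state occupancy", {
  cfg0 <- toy_config(rating_noise = 0)
  sb <- data.frame(subject = "s01", block = 1:5)
  r <- make_ratings(sb, c(0, 0.25, 0.5, 0.75, 1), cfg0, seed = 21)
  expect_identical(r$tiredness[1], 1L)
  expect_identical(r$tiredness[5], 7L)
  expect_true(all(diff(r$tiredness) >= 0))
  expect_true(all(r$success %in% 1:7 & r$focus %in% 1:7))
  # default noise: rank correlation with occupancy stays clearly positive
  cfg <- generator_config()
  set.seed(22)
  occ <- stats::rbeta(150, 2, 6)
  sb2 <- data.frame(subject = rep(sprintf("s%02d", 1:25), each = 6),
                    block = rep(1:6, 25))
  r2 <- make_ratings(sb2, occ, cfg, seed = 23)
  expect_gt(cor(r2$tiredness, occ, method = "spearman"), 0.2)
})

test_that("templates are validated and unrealizable ones are refused", {
  cfg <- generator_config()
  for (tm in cfg$state_templates) {
    expect_equal(tm, t(tm))
    expect_equal(diag(tm), rep(1, 42))
    expect_true(all(abs(tm) <= 1 + 1e-12))
  }
  # a realizable template round-trips through offset fitting
  good <- lapply(1:2, function(s) cfg$state_templates[[s]][1:8, 1:8])
  msgs <- capture_messages(
    cfg_t <- generator_config(n_rois = 8, n_states = 2,
                              state_templates = good,
                              transition_matrix = matrix(0.5, 2, 2),
                              favorable_state = 1, tired_state = 2))
  expect_match(paste(msgs, collapse = " "), "approximation error")
  expect_lt(max(cfg_t$template_error), 1e-3)
  # three mutually antiphase ROIs cannot exist on the circle
  bad <- matrix(-1, 3, 3); diag(bad) <- 1
  expect_error(
    suppressMessages(generator_config(
      n_rois = 3, n_states = 2,
      state_templates = list(diag(3) * 0 + diag(3), bad),
      transition_matrix = matrix(0.5, 2, 2),
      favorable_state = 1, tired_state = 2)),
    "not realizable")
  expect_error(generator_config(psychometric = list(alpha = 0, beta = 0.8,
                                                    lapse = 0.2, guess = 0)),
               "lapse")
  expect_error(generator_config(state_boost = 0.9), "state_boost")
})

test_that("subject simulations assemble trials, ratings, and latent truth coherently", {
  cfg <- generator_config(n_subjects = 2)
  sub <- simulate_subject(cfg, seed = 24, subject_id = "s07", bold = FALSE)
  expect_identical(nrow(sub$trials), 198L)
  expect_identical(nrow(sub$ratings), 6L)
  expect_identical(length(sub$task), 6L)
  st <- state_table(sub)
  expect_identical(nrow(st), 6L * 480L)
  # trial state_at_onset matches the latent chain at the onset volume
  i <- 25
  b <- sub$trials$block[i]
  v <- floor(sub$trials$onset[i]) + 1
  expect_identical(sub$trials$state_at_onset[i],
                   sub$task[[b]]$latent$states[v])
  # reproducible under the same seed
  sub2 <- simulate_subject(cfg, seed = 24, subject_id = "s07", bold = FALSE)
  expect_identical(sub$trials, sub2$trials)
})
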