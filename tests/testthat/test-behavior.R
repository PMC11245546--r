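test_that("BH adjustment matches the step-up definition", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(fdr_bh(0.037), 0.037)
  expect_equal(fdr_bh(rep(1, 4)), rep(1, 4))
  expect_identical(fdr_bh(numeric(0)), numeric(0))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  res <- fdr_bh(c(0.04, 0.001, 0.2), q = 0.05)
  expect_identical(res$reject, c(FALSE, TRUE, FALSE))
  set.seed(30)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(fdr_bh(p), oracle_bh(p))
  }
})

test_that("arcsine transform hits the textbook anchors", {
  expect_equal(arcsine_rate(0), 0)
  expect_equal(arcsine_rate(1), pi / 2)
  expect_equal(arcsine_rate(0.5), pi / 4)
  expect_error(arcsine_rate(1.01), "\\[0, 1\\]")
})

test_that("trials join the volume whose acquisition interval contains the onset", {
  states <- data.frame(subject = "s01", block = 1, volume = 1:20,
                       time_s = 0:19, label = rep(1:4, 5))
  attr(states, "tr") <- 1
  trials <- data.frame(subject = "s01", block = 1, trial = 1:3,
                       onset = c(10.2, 11.0, 0.4),
                       snr = c("-9", "-9", "-7"),
                       detected = c(TRUE, FALSE, TRUE))
  j <- join_patterns(trials, states)
  # onset 10.2 s -> volume interval [10, 11) -> row 11; 11.0 -> row 12 (half-open)
  expect_identical(j$pattern_at_onset, states$label[c(11, 12, 1)])
  # constant labels propagate to every trial
  states$label <- 3L
  expect_true(all(join_patterns(trials, states)$pattern_at_onset == 3L))
  trials$onset[2] <- 25
  expect_error(join_patterns(trials, states), "trial 2")
})

test_that("detection-rate cells count exactly and pool to the marginals", {
  tt <- data.frame(subject = "s01", block = 1, trial = 1:5,
                   onset = 1:5 * 14,
                   snr = c("-9", "-9", "-9", "-9", "catch"),
                   detected = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                   prev_detected = c(NA, TRUE, TRUE, TRUE, FALSE),
                   state_at_onset = 1L)
  rt <- detection_rates(tt)
  expect_equal(rt$cells$rate, 0.75)
  expect_equal(rt$overall$rate[rt$overall$snr == "catch"], 0)
  # random toy table: trial-count-weighted cell rates equal the marginal
  set.seed(31)
  toy <- data.frame(subject = sample(c("a", "b", "c"), 400, TRUE),
                    block = 1, trial = 1:400, onset = 1:400,
                    snr = sample(c("-7", "-9", "-11"), 400, TRUE),
                    detected = runif(400) < 0.5,
                    prev_detected = TRUE,
                    state_at_onset = sample(1:3, 400, TRUE))
  rt2 <- detection_rates(toy)
  for (s in c("-7", "-9", "-11")) {
    cells <- rt2$cells[rt2$cells$snr == s, ]
    expect_equal(sum(cells$rate * cells$n_trials) / sum(cells$n_trials),
                 rt2$overall$rate[rt2$overall$snr == s])
  }
  # degenerate rates are exact
  expect_true(all(rt2$cells$rate >= 0 & rt2$cells$rate <= 1))
})

test_that("signed-rank comparisons against the baseline match enumeration", {
  cells <- data.frame(subject = c("a", "b", "c"), pattern = 1, snr = "-9",
                      n_trials = 10, n_detected = c(6.8, 7.8, 8.8),
                      rate = 0.58 + c(0.1, 0.2, 0.3))
  res <- compare_to_baseline(cells, baseline = 0.58)
  expect_equal(unname(res$V), 6)
  expect_equal(res$p, 0.125)  # = 1/8, all-positive pattern of three signs
  expect_false(res$unreliable)  # three nonzero differences is the minimum
  # all-zero differences are skipped
  cells$n_detected <- 5.8
  res0 <- compare_to_baseline(cells, baseline = 0.58)
  expect_true(res0$skipped)
  # antisymmetric data sit at chance
  d <- c(0.11, 0.12, 0.13, -0.11, -0.12, -0.13)
  cells2 <- data.frame(subject = letters[1:6], pattern = 1, snr = "-9",
                       n_trials = 10, n_detected = 5, rate = 0.58 + d)
  res2 <- compare_to_baseline(cells2, baseline = 0.58)
  expect_gt(res2$p, 0.3)
})

test_that("wilcox.test exact path agrees with full sign-pattern enumeration", {
  set.seed(32)
  for (i in 1:500) {
    n <- sample(3:10, 1)
    d <- round(runif(n, 0.01, 1), 6) * sample(c(-1, 1), n, TRUE)
    if (anyDuplicated(abs(d))) next
    for (alt in c("two.sided", "greater")) {
      got <- stats::wilcox.test(d, alternative = alt)$p.value
      want <- oracle_signrank(d, alt)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("the rate model recovers weighted least squares when subjects are exchangeable", {
  # balanced cells, no subject effect: the random intercept collapses to zero
  # and the mixed fit must reproduce plain weighted least squares
  set.seed(33)
  grid <- expand.grid(subject = sprintf("s%02d", 1:8), pattern = 1:3,
                      snr = c("-7", "-9", "-11"),
                      stringsAsFactors = FALSE)
  true_p <- c("-7" = 0.9, "-9" = 0.55, "-11" = 0.2)
  grid$n_trials <- 20
  grid$n_detected <- rbinom(nrow(grid), 20, true_p[grid$snr])
  grid$rate <- grid$n_detected / grid$n_trials
  m <- suppressMessages(fit_rate_model(grid, contrasts = FALSE))
  if (m$singular) {
    df <- data.frame(pattern = factor(grid$pattern),
                     snr = factor(grid$snr, levels = c("-11", "-9", "-7")),
                     y = arcsine_rate(grid$rate), w = grid$n_trials)
    wls <- stats::lm(y ~ pattern * snr, data = df, weights = w)
    expect_equal(unname(lme4::fixef(m$model)), unname(coef(wls)),
                 tolerance = 1e-6)
  }
  expect_identical(m$transform, "arcsine")
  expect_true(all(m$term_tests$p >= 0 & m$term_tests$p <= 1))
})

test_that("RT filtering is closed at both ends and the SNR effect keeps its sign", {
  tt <- data.frame(subject = rep(c("a", "b"), each = 6), block = 1,
                   trial = 1:12, onset = 1:12,
                   snr = rep(c("-7", "-9", "-11"), 4), detected = TRUE,
                   rt = rep(c(0.3, 2.5, 0.4, 2.0, 1.0, 1.2), 2),
                   prev_detected = TRUE,
                   state_at_onset = rep(1:2, 6))
  # degenerate 12-trial fixture: convergence warnings are expected noise here
  m <- suppressWarnings(suppressMessages(fit_rt_model(tt, contrasts = FALSE)))
  expect_identical(m$n_trials_used, 8L)  # 0.3 and 2.5 excluded, bounds kept
  expect_error(fit_rt_model(tt[tt$rt > 3, ]), "survive")
  # planted ordering: faster at -7 than -11 recovers a negative 1/RT slope
  cfg <- generator_config(n_subjects = 8)
  sim <- simulate_study(cfg, seed = 34, bold = FALSE)
  mm <- suppressMessages(fit_rt_model(sim$trials))
  s <- mm$contrasts[mm$contrasts$factor == "snr" &
                      mm$contrasts$contrast == "(snr-11) - (snr-7)", ]
  expect_lt(s$estimate, 0)  # 1/RT lower at -11: slower responses
  expect_lt(s$p, 0.05)
})

test_that("occupancy windows count patterns exactly and sum to one", {
  states <- data.frame(subject = rep(c("a", "b"), each = 40),
                       block = 1, volume = rep(1:40, 2), time_s = rep(0:39, 2),
                       label = 2L)
  attr(states, "tr") <- 1
  trials <- data.frame(subject = rep(c("a", "b"), each = 2), block = 1,
                       trial = rep(1:2, 2), onset = c(5.5, 20.2, 6.1, 21.0),
                       snr = "-9", detected = c(TRUE, FALSE, TRUE, FALSE))
  ps <- poststim_occupancy(trials, states, window = 9, k = 3)
  m <- ps$subject_means
  expect_true(all(m$prob[m$pattern == 2] == 1))
  expect_true(all(m$prob[m$pattern != 2] == 0))
  sums <- aggregate(prob ~ subject + condition, data = m, FUN = sum)
  expect_true(all(abs(sums$prob - 1) < 1e-9))
  # identical label sequences leave nothing to test
  expect_true(all(is.na(ps$tests$p)))
  # windows that run off the end are dropped and counted
  trials2 <- trials
  trials2$onset[2] <- 39.5
  ps2 <- poststim_occupancy(trials2, states, window = 9, k = 3)
  expect_identical(ps2$dropped, 1L)
})

test_that("time-resolved profiles cover the full offset grid with per-pattern FDR", {
  set.seed(35)
  states <- data.frame(subject = rep(sprintf("s%d", 1:4), each = 200),
                       block = 1, volume = rep(1:200, 4),
                       time_s = rep(0:199, 4),
                       label = sample(1:3, 800, TRUE))
  attr(states, "tr") <- 1
  trials <- expand.grid(subject = sprintf("s%d", 1:4), trial = 1:10)
  trials$block <- 1
  trials$onset <- 20 + trials$trial * 15 + runif(nrow(trials))
  trials$snr <- "-9"
  trials$detected <- rep(rep(c(TRUE, FALSE), each = 4), 5)
  tr <- time_resolved_occupancy(trials, states, offsets = -3:9, k = 3)
  expect_identical(nrow(tr$tests), 13L * 3L)  # 13 offsets per pattern
  expect_identical(sort(unique(tr$tests$offset)), -3:9)
  # FDR applied within each pattern across its 13 offsets
  for (p in 1:3) {
    g <- tr$tests[tr$tests$pattern == p, ]
    expect_equal(g$p_fdr, fdr_bh(g$p))
  }
})

test_that("rating correlations recover monotone association and flag degenerate inputs", {
  occ <- data.frame(subject = rep("s", 12), block = 1:12, pattern = 1,
                    prob = (1:12) / 13)
  ratings <- data.frame(subject = "s", block = 1:12,
                        tiredness = 1:12, success = 12:1, focus = 4)
  rc <- suppressWarnings(
    ratings_correlation(occ, ratings,
                        rating_cols = c("tiredness", "success", "focus")))
  expect_equal(rc$rho[rc$rating == "tiredness"], 1)
  expect_equal(rc$rho[rc$rating == "success"], -1)
  expect_true(is.na(rc$rho[rc$rating == "focus"]))
  expect_error(ratings_correlation(occ[1:5, ], ratings[1:5, ]),
               "at least 10")
})
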