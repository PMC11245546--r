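#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment: adjusted p for the i-th smallest
#' of m p values is `min over j >= i of p_(j) * m / j`, capped at 1
#' (delegated to [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p values in \[0, 1\] (NAs pass through).
#' @param q optional FDR level; when supplied the rejection set is returned
#'   alongside the adjusted values.
#' @return Adjusted p values (same length/order as input), or, when `q` is
#'   given, a list with `p_adjusted` and logical `reject`.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05))
#' @export
fdr_bh <- function(p_values, q = NULL) {
  if (length(p_values) == 0L) {
    adj <- numeric(0)
  } else {
    ok <- !is.na(p_values)
    if (any(p_values[ok] < 0 | p_values[ok] > 1))
      stop("p values must lie in [0, 1]")
    adj <- stats::p.adjust(p_values, method = "BH")
  }
  if (is.null(q)) return(adj)
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Arcsine transform of a proportion
#'
#' `asin(sqrt(p))`, the variance-stabilizing transform applied to detection
#' rates before linear modeling.
#'
#' @param p proportions in \[0, 1\].
#' @return Transformed values in \[0, pi/2\].
#' @examples
#' arcsine_rate(c(0, 0.5, 1))
#' @export
arcsine_rate <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Attach the pattern at stimulus time to each trial
#'
#' The pattern "at stimulus time" is the label of the volume whose
#' acquisition interval `[k*TR, (k+1)*TR)` contains the trial onset.
#'
#' @param trials a trial table (from [simulate_observer()],
#'   [simulate_study()]`$trials`, or a user CSV of the same shape).
#' @param states a long state table ([state_table()]): columns `subject`,
#'   `block`, `volume`, `label`; attribute or argument `tr`.
#' @param tr repetition time (seconds); defaults to the state table's
#'   attribute.
#' @return The trial table with a `pattern_at_onset` column.
#' @export
join_patterns <- function(trials, states, tr = attr(states, "tr")) {
  if (is.null(tr)) tr <- 1
  vol <- floor(trials$onset / tr) + 1L
  key_t <- paste(trials$subject, trials$block, vol, sep = "\r")
  key_s <- paste(states$subject, states$block, states$volume, sep = "\r")
  idx <- match(key_t, key_s)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf(
      "trial %d of block %d (subject %s): onset %.1f s has no labeled volume",
      trials$trial[bad], trials$block[bad], trials$subject[bad],
      trials$onset[bad]))
  }
  trials$pattern_at_onset <- states$label[idx]
  trials
}

# Pattern column to condition on: fitted labels when present, else the
# planted latent truth.
pattern_col <- function(trials) {
  if ("pattern_at_onset" %in% names(trials)) "pattern_at_onset"
  else if ("state_at_onset" %in% names(trials)) "state_at_onset"
  else stop("trials carry neither 'pattern_at_onset' nor 'state_at_onset'; ",
            "run join_patterns() first")
}

#' Detection-rate table
#'
#' Exact counts and proportions of detected trials per (subject, pattern,
#' SNR) cell — catch trials excluded from cells — plus overall per-SNR
#' marginal rates including the catch false-alarm rate.
#'
#' @param trials a trial table with a pattern column (`pattern_at_onset`, or
#'   the planted `state_at_onset` as fallback).
#' @param by_prev additionally split cells by previous-trial detection
#'   status (block-initial trials, whose status is undefined, are dropped).
#' @return Object of class `rate_table`: `cells` (subject, pattern, snr
#'   \[, prev_detected\], n_trials, n_detected, rate) and `overall` (snr, n,
#'   rate).
#' @export
detection_rates <- function(trials, by_prev = FALSE) {
  if (nrow(trials) == 0L) stop("empty trial table")
  pc <- pattern_col(trials)
  stim <- trials[trials$snr != "catch", , drop = FALSE]
  keys <- list(subject = stim$subject, pattern = stim[[pc]], snr = stim$snr)
  if (by_prev) {
    keep <- !is.na(stim$prev_detected)
    stim <- stim[keep, , drop = FALSE]
    keys <- list(subject = stim$subject, pattern = stim[[pc]],
                 snr = stim$snr, prev_detected = stim$prev_detected)
  }
  cells <- stats::aggregate(stim$detected, by = keys,
                            FUN = function(d) c(n = length(d), k = sum(d)))
  cells <- cbind(cells[names(cells) != "x"],
                 n_trials = cells$x[, "n"],
                 n_detected = cells$x[, "k"])
  cells$rate <- cells$n_detected / cells$n_trials
  overall <- stats::aggregate(trials$detected, by = list(snr = trials$snr),
                              FUN = function(d) c(n = length(d), k = sum(d)))
  overall <- data.frame(snr = overall$snr, n = overall$x[, "n"],
                        rate = overall$x[, "k"] / overall$x[, "n"])
  structure(list(cells = cells, overall = overall, by_prev = by_prev),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat("<rate_table> overall detection rates:\n")
  print(transform(x$overall, rate = round(rate, 3)), row.names = FALSE)
  cat(sprintf("%d (subject, pattern, snr%s) cells\n", nrow(x$cells),
              if (x$by_prev) ", prev" else ""))
  invisible(x)
}

snr_factor <- function(x) factor(x, levels = c("-11", "-9", "-7"))

# Paired Cohen's d on subject-level arcsine rates for pattern pairs within
# an SNR level: mean of within-subject differences / SD of the differences.
paired_d <- function(cells, snr_level, p1, p2, value = "y") {
  a <- cells[cells$snr == snr_level & cells$pattern == p1, ]
  b <- cells[cells$snr == snr_level & cells$pattern == p2, ]
  common <- intersect(a$subject, b$subject)
  if (length(common) < 2L) return(NA_real_)
  d <- a[[value]][match(common, a$subject)] -
    b[[value]][match(common, b$subject)]
  if (stats::sd(d) == 0) return(NA_real_)
  mean(d) / stats::sd(d)
}

#' Linear mixed model for state-conditioned detection rates
#'
#' Fits arcsine-transformed per-cell detection rates with a subject random
#' intercept, pattern and SNR (and optionally previous-detection status) as
#' categorical fixed effects, observations weighted by per-cell trial
#' counts. Terms are tested with Type-II Wald chi-square tests; pairwise
#' pattern contrasts within each SNR level get FDR (Benjamini-Hochberg)
#' corrected p values — the correction family is the set of pattern pairs
#' within one SNR — and a paired Cohen's d on the subject-level transformed
#' rates.
#'
#' @param rates a [detection_rates()] result (built with
#'   `by_prev = include_prev`), or a cell data.frame of the same shape.
#' @param include_prev include the previous-detection fixed effect and its
#'   interactions.
#' @param contrasts compute pairwise pattern contrasts (skip for speed in
#'   replicate simulations).
#' @return Object of class `state_behavior_model`: `model` (the lmer fit),
#'   `term_tests` (term, chisq, df, p), `contrasts` (snr, pattern pair,
#'   estimate, t, p, p_fdr, cohens_d), `transform = "arcsine"`,
#'   `weights = "n_trials"`, `singular` flag.
#' @export
fit_rate_model <- function(rates, include_prev = FALSE, contrasts = TRUE) {
  cells <- if (inherits(rates, "rate_table")) rates$cells else rates
  if (include_prev && !"prev_detected" %in% names(cells))
    stop("include_prev = TRUE needs cells split by previous detection ",
         "(detection_rates(..., by_prev = TRUE))")
  if (length(unique(cells$subject)) < 2L) stop("need at least 2 subjects")
  df <- data.frame(
    subject = factor(cells$subject),
    pattern = factor(cells$pattern),
    snr = snr_factor(cells$snr),
    y = arcsine_rate(cells$rate),
    w = cells$n_trials)
  form <- y ~ pattern * snr + (1 | subject)
  if (include_prev) {
    df$prev <- factor(cells$prev_detected)
    form <- y ~ pattern * snr + prev + prev:pattern + prev:snr + (1 | subject)
  }
  fit <- lme4::lmer(form, data = df, weights = w, REML = TRUE)
  singular <- lme4::isSingular(fit)
  an <- car::Anova(fit, type = 2)
  term_tests <- data.frame(term = rownames(an), chisq = an[["Chisq"]],
                           df = an[["Df"]], p = an[["Pr(>Chisq)"]],
                           row.names = NULL)

  ctr <- NULL
  if (contrasts) {
    em <- emmeans::emmeans(fit, ~ pattern | snr, lmer.df = "asymptotic")
    pr <- summary(emmeans::contrast(em, method = "pairwise", adjust = "none"))
    stat <- if (!is.null(pr$t.ratio)) pr$t.ratio else pr$z.ratio
    pr$stat <- stat
    # subject-level cells for the paired effect size (collapse prev split)
    dcells <- stats::aggregate(
      cbind(n_detected, n_trials) ~ subject + pattern + snr,
      data = cells, FUN = sum)
    dcells$y <- arcsine_rate(dcells$n_detected / dcells$n_trials)
    pairs <- do.call(rbind, lapply(split(pr, pr$snr), function(g) {
      g$p_fdr <- fdr_bh(g$p.value)
      g
    }))
    dvals <- mapply(function(ct, sn) {
      pp <- sub("^pattern", "", strsplit(ct, " - ")[[1]])
      paired_d(dcells, as.character(sn), pp[1], pp[2])
    }, as.character(pairs$contrast), as.character(pairs$snr))
    ctr <- data.frame(snr = pairs$snr, contrast = pairs$contrast,
                      estimate = pairs$estimate, t = pairs$stat,
                      p = pairs$p.value, p_fdr = pairs$p_fdr,
                      cohens_d = dvals, row.names = NULL)
  }
  structure(
    list(model = fit, term_tests = term_tests, contrasts = ctr,
         transform = "arcsine", weights = "n_trials", singular = singular),
    class = "state_behavior_model")
}

#' @export
print.state_behavior_model <- function(x, ...) {
  cat(sprintf("<state_behavior_model> transform: %s, weights: %s%s\n",
              x$transform, x$weights,
              if (x$singular) " [singular random-effect fit]" else ""))
  cat("Type-II Wald chi-square tests:\n")
  print(transform(x$term_tests, chisq = round(chisq, 2),
                  p = signif(p, 3)), row.names = FALSE)
  if (!is.null(x$contrasts)) {
    sig <- x$contrasts[!is.na(x$contrasts$p_fdr) & x$contrasts$p_fdr < 0.05, ]
    cat(sprintf("%d pairwise contrasts (%d with FDR p < 0.05)\n",
                nrow(x$contrasts), nrow(sig)))
  }
  invisible(x)
}

#' Compare per-pattern threshold detection rates to a fixed baseline
#'
#' One-sided Wilcoxon signed-rank test, per pattern, of subject detection
#' rates at the threshold SNR against a scalar baseline (the staircase target
#' rate). Zero differences are dropped; the exact distribution is used for
#' small samples without ties, otherwise the normal approximation with
#' continuity correction. Patterns with fewer than 3 nonzero differences are
#' flagged unreliable.
#'
#' @param rates a [detection_rates()] result or cell data.frame.
#' @param baseline scalar baseline detection rate (default 0.58).
#' @param snr_level threshold SNR (default `"-9"`).
#' @param alternative `"greater"` tests elevation above baseline.
#' @return data.frame `pattern`, `n` (nonzero differences), `V`, `p`,
#'   `unreliable`, `skipped`.
#' @export
compare_to_baseline <- function(rates, baseline = 0.58, snr_level = "-9",
                                alternative = "greater") {
  cells <- if (inherits(rates, "rate_table")) rates$cells else rates
  cells <- cells[cells$snr == snr_level, , drop = FALSE]
  if (any(duplicated(paste(cells$subject, cells$pattern))))
    cells <- stats::aggregate(
      cbind(n_detected, n_trials) ~ subject + pattern, data = cells, FUN = sum)
  cells$rate <- cells$n_detected / cells$n_trials
  out <- lapply(sort(unique(cells$pattern)), function(p) {
    x <- cells$rate[cells$pattern == p]
    nz <- sum(x != baseline)
    if (nz == 0L)
      return(data.frame(pattern = p, n = 0L, V = NA_real_, p = NA_real_,
                        unreliable = TRUE, skipped = TRUE))
    wt <- suppressWarnings(
      stats::wilcox.test(x, mu = baseline, alternative = alternative,
                         correct = TRUE))
    data.frame(pattern = p, n = nz, V = unname(wt$statistic),
               p = wt$p.value, unreliable = nz < 3L, skipped = FALSE)
  })
  do.call(rbind, out)
}

#' Linear mixed model for state-conditioned reaction times
#'
#' Keeps detected non-catch trials with RT inside `rt_range` (closed
#' interval), aggregates mean inverse RT (1/RT) per (subject, pattern, SNR)
#' cell, and fits the same weighted random-intercept model as
#' [fit_rate_model()] with pattern and SNR main effects. Wald chi-square
#' term tests plus FDR-corrected pairwise contrasts (within factor) and
#' paired Cohen's d.
#'
#' @param trials a trial table with a pattern column.
#' @param rt_range RT filter in seconds (default `c(0.4, 2)`, both ends
#'   included).
#' @param contrasts compute pairwise contrasts.
#' @return A `state_behavior_model` with `transform = "inverse_rt"`.
#' @export
fit_rt_model <- function(trials, rt_range = c(0.4, 2), contrasts = TRUE) {
  pc <- pattern_col(trials)
  keep <- trials$snr != "catch" & trials$detected & !is.na(trials$rt) &
    trials$rt >= rt_range[1] & trials$rt <= rt_range[2]
  tt <- trials[keep, , drop = FALSE]
  if (nrow(tt) == 0L) stop("no trials survive the RT filter [",
                           rt_range[1], ", ", rt_range[2], "] s")
  agg <- stats::aggregate(
    list(inv_rt = 1 / tt$rt),
    by = list(subject = tt$subject, pattern = tt[[pc]], snr = tt$snr),
    FUN = mean)
  nn <- stats::aggregate(
    list(n = tt$rt),
    by = list(subject = tt$subject, pattern = tt[[pc]], snr = tt$snr),
    FUN = length)
  agg$n <- nn$n
  df <- data.frame(subject = factor(agg$subject),
                   pattern = factor(agg$pattern), snr = snr_factor(agg$snr),
                   y = agg$inv_rt, w = agg$n)
  fit <- lme4::lmer(y ~ pattern + snr + (1 | subject), data = df,
                    weights = w, REML = TRUE)
  an <- car::Anova(fit, type = 2)
  term_tests <- data.frame(term = rownames(an), chisq = an[["Chisq"]],
                           df = an[["Df"]], p = an[["Pr(>Chisq)"]],
                           row.names = NULL)
  ctr <- NULL
  if (contrasts) {
    agg$y <- agg$inv_rt
    res <- list()
    for (fac in c("pattern", "snr")) {
      em <- emmeans::emmeans(fit, stats::reformulate(fac),
                             lmer.df = "asymptotic")
      pr <- summary(emmeans::contrast(em, "pairwise", adjust = "none"))
      pr$stat <- if (!is.null(pr$t.ratio)) pr$t.ratio else pr$z.ratio
      pr$p_fdr <- fdr_bh(pr$p.value)
      dvals <- vapply(as.character(pr$contrast), function(ct) {
        pp <- strsplit(ct, " - ")[[1]]
        pp <- sub(paste0("^", fac), "", gsub("^\\(|\\)$", "", pp))
        if (fac == "pattern") {
          a <- agg[agg$pattern == pp[1], ]; b <- agg[agg$pattern == pp[2], ]
          key <- "subject"
        } else {
          a <- agg[agg$snr == pp[1], ]; b <- agg[agg$snr == pp[2], ]
          a <- stats::aggregate(y ~ subject, a, mean)
          b <- stats::aggregate(y ~ subject, b, mean)
        }
        common <- intersect(a$subject, b$subject)
        if (length(common) < 2L) return(NA_real_)
        d <- a$y[match(common, a$subject)] - b$y[match(common, b$subject)]
        if (stats::sd(d) == 0) NA_real_ else mean(d) / stats::sd(d)
      }, 1)
      res[[fac]] <- data.frame(factor = fac, contrast = pr$contrast,
                               estimate = pr$estimate, t = pr$stat,
                               p = pr$p.value, p_fdr = pr$p_fdr,
                               cohens_d = dvals, row.names = NULL)
    }
    ctr <- do.call(rbind, res)
    rownames(ctr) <- NULL
  }
  structure(
    list(model = fit, term_tests = term_tests, contrasts = ctr,
         transform = "inverse_rt", weights = "n_trials",
         singular = lme4::isSingular(fit), n_trials_used = nrow(tt)),
    class = "state_behavior_model")
}

# Per-trial pattern occupancy over a set of volume offsets relative to the
# onset volume. Returns NULL when any needed volume is missing.
trial_occupancy <- function(labels_block, v0, offsets, k) {
  vols <- v0 + offsets
  if (any(vols < 1L) || any(vols > length(labels_block))) return(NULL)
  tabulate(labels_block[vols], k) / length(vols)
}

occupancy_by_subject <- function(trials, states, offsets, k, tr) {
  pc_labels <- split(states, list(states$subject, states$block), drop = TRUE)
  lab_of <- function(su, bl) {
    g <- pc_labels[[paste(su, bl, sep = ".")]]
    if (is.null(g)) NULL else g$label[order(g$volume)]
  }
  acc <- list()
  dropped <- 0L
  for (i in seq_len(nrow(trials))) {
    labs <- lab_of(trials$subject[i], trials$block[i])
    if (is.null(labs)) stop("no state labels for subject ",
                            trials$subject[i], " block ", trials$block[i])
    v0 <- floor(trials$onset[i] / tr) + 1L
    occ <- trial_occupancy(labs, v0, offsets, k)
    if (is.null(occ)) { dropped <- dropped + 1L; next }
    acc[[length(acc) + 1L]] <- data.frame(
      subject = trials$subject[i],
      condition = if (trials$detected[i]) "detected" else "undetected",
      pattern = seq_len(k), prob = occ, stringsAsFactors = FALSE)
  }
  if (!length(acc)) stop("no trials with a complete occupancy window")
  per_trial <- do.call(rbind, acc)
  means <- stats::aggregate(
    prob ~ subject + condition + pattern, data = per_trial, FUN = mean)
  list(means = means, dropped = dropped, n_trials = length(acc))
}

paired_wilcoxon_by_pattern <- function(means, k) {
  out <- lapply(seq_len(k), function(p) {
    g <- means[means$pattern == p, ]
    d <- g[g$condition == "detected", ]
    u <- g[g$condition == "undetected", ]
    common <- intersect(d$subject, u$subject)
    excluded <- length(unique(g$subject)) - length(common)
    if (length(common) < 2L)
      return(data.frame(pattern = p, n_subjects = length(common),
                        V = NA_real_, p = NA_real_, excluded = excluded))
    x <- d$prob[match(common, d$subject)]
    y <- u$prob[match(common, u$subject)]
    if (all(x == y))
      return(data.frame(pattern = p, n_subjects = length(common),
                        V = 0, p = NA_real_, excluded = excluded))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, alternative = "two.sided"))
    data.frame(pattern = p, n_subjects = length(common),
               V = unname(wt$statistic), p = wt$p.value,
               excluded = excluded)
  })
  do.call(rbind, out)
}

#' Post-stimulus pattern occupancy, detected vs. undetected
#'
#' For each threshold (SNR -9) trial, the fraction of the `window` seconds
#' of volumes strictly following the onset volume (offsets +1..+window at TR
#' steps) spent in each pattern; subject-averaged per condition and compared
#' between detected and undetected trials with a paired two-sided Wilcoxon
#' signed-rank test per pattern. Trials whose window runs past the end of
#' the block are dropped (counted in `dropped`); subjects lacking either
#' condition are excluded from that pattern's test.
#'
#' @param trials trial table (threshold trials are selected internally).
#' @param states long state table ([state_table()] or labeled task runs).
#' @param window post-stimulus window length in seconds (default 9).
#' @param k number of patterns (default: max label in `states`).
#' @param tr repetition time; defaults to the state table attribute.
#' @param snr_level which SNR defines the threshold trials.
#' @return Object of class `occupancy_comparison`: `subject_means`
#'   (subject, condition, pattern, prob), `tests` (pattern, n_subjects, V,
#'   p, excluded), `dropped`, `offsets`.
#' @export
poststim_occupancy <- function(trials, states, window = 9,
                               k = max(states$label),
                               tr = attr(states, "tr"), snr_level = "-9") {
  if (is.null(tr)) tr <- 1
  offsets <- seq_len(round(window / tr))
  tt <- trials[trials$snr == snr_level, , drop = FALSE]
  if (nrow(tt) == 0L) stop("no trials at SNR ", snr_level)
  occ <- occupancy_by_subject(tt, states, offsets, k, tr)
  structure(
    list(subject_means = occ$means,
         tests = paired_wilcoxon_by_pattern(occ$means, k),
         dropped = occ$dropped, n_trials = occ$n_trials, offsets = offsets),
    class = "occupancy_comparison")
}

#' @export
print.occupancy_comparison <- function(x, ...) {
  cat(sprintf(
    "<occupancy_comparison> offsets %+d..%+d volumes, %d trials (%d dropped)\n",
    min(x$offsets), max(x$offsets), x$n_trials, x$dropped))
  print(transform(x$tests, p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Time-resolved pattern occupancy around threshold stimuli
#'
#' At each integer-TR offset in `offsets` (default -3..+9 volumes around the
#' onset volume), the per-subject probability of each pattern across detected
#' and undetected threshold trials, compared condition-wise with paired
#' two-sided Wilcoxon tests; p values are FDR-corrected across offsets
#' within each pattern.
#'
#' @inheritParams poststim_occupancy
#' @param offsets volume offsets relative to the onset volume.
#' @return Object of class `occupancy_profile`: `profile` (subject,
#'   condition, pattern, offset, prob), `tests` (pattern, offset,
#'   n_subjects, V, p, p_fdr), `dropped`.
#' @export
time_resolved_occupancy <- function(trials, states, offsets = -3:9,
                                    k = max(states$label),
                                    tr = attr(states, "tr"),
                                    snr_level = "-9") {
  if (is.null(tr)) tr <- 1
  tt <- trials[trials$snr == snr_level, , drop = FALSE]
  if (nrow(tt) == 0L) stop("no trials at SNR ", snr_level)
  prof <- list(); tests <- list(); dropped_total <- 0L
  for (off in offsets) {
    occ <- occupancy_by_subject(tt, states, off, k, tr)
    dropped_total <- dropped_total + occ$dropped
    m <- occ$means
    m$offset <- off
    prof[[length(prof) + 1L]] <- m
    te <- paired_wilcoxon_by_pattern(occ$means, k)
    te$offset <- off
    tests[[length(tests) + 1L]] <- te
  }
  tests <- do.call(rbind, tests)
  tests <- do.call(rbind, lapply(split(tests, tests$pattern), function(g) {
    g$p_fdr <- fdr_bh(g$p)
    g
  }))
  rownames(tests) <- NULL
  structure(
    list(profile = do.call(rbind, prof),
         tests = tests[order(tests$pattern, tests$offset), ],
         dropped = dropped_total, offsets = offsets),
    class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf("<occupancy_profile> offsets %d..%d, %d pattern x offset tests\n",
              min(x$offsets), max(x$offsets), nrow(x$tests)))
  sig <- x$tests[!is.na(x$tests$p_fdr) & x$tests$p_fdr < 0.05, ]
  if (nrow(sig)) {
    cat("FDR-significant (p_fdr < 0.05):\n")
    print(transform(sig, p = signif(p, 3), p_fdr = signif(p_fdr, 3)),
          row.names = FALSE)
  } else cat("no FDR-significant pattern x offset cells\n")
  invisible(x)
}

#' Per-block pattern occupancy
#'
#' Fraction of each block's volumes assigned to each pattern, from a long
#' state table.
#'
#' @param states a [state_table()] data.frame.
#' @param k number of patterns.
#' @return data.frame `subject`, `block`, `pattern`, `prob`.
#' @export
block_occupancy <- function(states, k = max(states$label)) {
  out <- lapply(split(states, list(states$subject, states$block),
                      drop = TRUE), function(g)
    data.frame(subject = g$subject[1L], block = g$block[1L],
               pattern = seq_len(k), prob = tabulate(g$label, k) / nrow(g),
               stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spearman correlations between pattern occupancy and subjective ratings
#'
#' Correlates per-block pattern occupancy with block-level ratings
#' (tiredness, success, focus) across pooled subject-blocks, with FDR
#' correction over the full pattern-by-rating grid. Constant rating vectors
#' have undefined correlations and are reported as missing.
#'
#' @param occupancy a [block_occupancy()] data.frame.
#' @param ratings data.frame `subject`, `block`, plus rating columns.
#' @param rating_cols which rating columns to use.
#' @return data.frame `pattern`, `rating`, `n`, `rho`, `p`, `p_fdr`.
#' @export
ratings_correlation <- function(occupancy, ratings,
                                rating_cols = c("tiredness", "success",
                                                "focus")) {
  merged <- merge(occupancy, ratings, by = c("subject", "block"))
  if (length(unique(paste(merged$subject, merged$block))) < 10L)
    stop("need at least 10 subject-blocks")
  out <- list()
  for (p in sort(unique(merged$pattern))) {
    g <- merged[merged$pattern == p, ]
    for (rc in rating_cols) {
      y <- g[[rc]]
      if (length(unique(y)) < 2L || length(unique(g$prob)) < 2L) {
        out[[length(out) + 1L]] <- data.frame(
          pattern = p, rating = rc, n = nrow(g), rho = NA_real_,
          p = NA_real_)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(g$prob, y, method = "spearman"))
      out[[length(out) + 1L]] <- data.frame(
        pattern = p, rating = rc, n = nrow(g),
        rho = unname(ct$estimate), p = ct$p.value)
    }
  }
  res <- do.call(rbind, out)
  res$p_fdr <- fdr_bh(res$p)
  res
}
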