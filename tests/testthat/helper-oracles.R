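# Independent oracles used across the suite. Deliberately naive: explicit
# DFT sums, exhaustive enumeration, direct formulas.

# Analytic signal by explicit O(n^2) DFT sums (one-sided spectrum doubling).
oracle_analytic <- function(x) {
  n <- length(x)
  idx <- 0:(n - 1)
  X <- vapply(idx, function(k)
    sum(x * exp(-2i * pi * k * idx / n)), complex(1))
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else h[2:((n + 1) / 2)] <- 2
  vapply(idx, function(t)
    sum(X * h * exp(2i * pi * idx * t / n)) / n, complex(1))
}

# Full phase-coherence chain, brute force: demean, oracle analytic signal,
# explicit cosine of phase differences per pair.
oracle_coherence <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  ph <- apply(x, 2, function(col) Arg(oracle_analytic(col)))
  p <- ncol(x)
  pairs <- t(utils::combn(p, 2))
  out <- matrix(NA_real_, nrow(x), nrow(pairs))
  for (r in seq_len(nrow(pairs)))
    out[, r] <- cos(ph[, pairs[r, 1]] - ph[, pairs[r, 2]])
  out
}

# Optimal 2-cluster L1 k-means by exhaustive bipartition search (n <= 12
# points): every nonempty split, coordinate-wise median centroids.
oracle_l1_kmeans2 <- function(x) {
  n <- nrow(x)
  stopifnot(n <= 12)
  best_cost <- Inf
  best <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {  # fix point 1 in cluster A (symmetry)
    inA <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2)))))
    if (!any(inA) || all(inA)) next
    ca <- apply(x[inA, , drop = FALSE], 2, stats::median)
    cb <- apply(x[!inA, , drop = FALSE], 2, stats::median)
    cost <- sum(abs(sweep(x[inA, , drop = FALSE], 2, ca))) +
      sum(abs(sweep(x[!inA, , drop = FALSE], 2, cb)))
    if (cost < best_cost) {
      best_cost <- cost
      best <- list(cost = cost, centroids = rbind(ca, cb), inA = inA)
    }
  }
  best
}

# Brute-force Benjamini-Hochberg step-up adjusted p values.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m))
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact one/two-sided signed-rank p by enumerating all 2^n sign patterns of
# the absolute-value ranks (requires nonzero differences, no tied |d|).
oracle_signrank <- function(d, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    pos <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sum(r[pos])
  }, 1)
  if (alternative == "greater") {
    mean(vs >= v_obs)
  } else {
    p <- 2 * min(mean(vs >= v_obs), mean(vs <= v_obs))
    min(1, p)
  }
}

# Mean silhouette width by the direct formula under Manhattan distance.
oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x, method = "manhattan"))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(d[i, labels == cl]), 1))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Small two-state test configuration (8 ROIs) with explicit offsets.
toy_config <- function(offsets = rbind(rep(0, 8),
                                       c(rep(0, 4), rep(pi, 4))),
                       transition_matrix = matrix(1 / nrow(offsets),
                                                  nrow(offsets),
                                                  nrow(offsets)),
                       tr = 1, ...) {
  generator_config(n_rois = ncol(offsets), n_states = nrow(offsets),
                   state_phase_offsets = offsets,
                   transition_matrix = transition_matrix, tr = tr,
                   favorable_state = 1, tired_state = 2,
                   ...)
}
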