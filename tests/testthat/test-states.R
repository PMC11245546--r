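make_blobs <- function(centers, n_per, sd, seed) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2,
          centers[i, ], "+")))
  list(x = x, truth = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("k = 1 gives the coordinate-wise median; duplicate data has zero cost", {
  set.seed(10)
  x <- matrix(rnorm(60), 20, 3)
  fit <- fit_states(x, k = 1, n_replicates = 3, seed = 1)
  expect_equal(unname(fit$centroids[1, ]), apply(x, 2, median))
  same <- matrix(1, 12, 4) * rep(c(1, 2, 3), each = 4)  # 3 distinct rows
  fit2 <- fit_states(same, k = 3, n_replicates = 5, seed = 2)
  expect_equal(fit2$inertia, 0)
})

test_that("two-cluster fits match the exhaustive bipartition oracle", {
  for (case in 1:5) {
    set.seed(20 + case)
    x <- rbind(matrix(rnorm(6 * 3, -3, 0.4), 6),
               matrix(rnorm(6 * 3, 3, 0.4), 6))
    fit <- fit_states(x, k = 2, n_replicates = 10, seed = case,
                      canonicalize = FALSE)
    oracle <- oracle_l1_kmeans2(x)
    expect_equal(fit$inertia, oracle$cost, tolerance = 1e-12)
    got <- fit$centroids[order(fit$centroids[, 1]), ]
    want <- oracle$centroids[order(oracle$centroids[, 1]), ]
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("within-cluster cost descends monotonically and labeling is idempotent", {
  b <- make_blobs(rbind(c(-2, 0, 1), c(2, 1, -1), c(0, -3, 2)), 30, 1.2, 31)
  fit <- fit_states(b$x, k = 3, n_replicates = 5, seed = 3)
  expect_true(all(diff(fit$cost_trace) <= 1e-9))
  s1 <- predict(fit, b$x)
  s2 <- predict(fit, b$x)
  expect_identical(s1$labels, s2$labels)
  # labeling the training data reproduces the training assignment
  expect_identical(s1$labels, fit$labels)
  expect_equal(s1$distances, fit$distances)
})

test_that("assignment ties break toward the lowest pattern index", {
  fit <- structure(list(centroids = rbind(c(0, 0), c(2, 0)), k = 2L,
                        d = 2L, pair_index = NULL),
                   class = "state_kmeans")
  s <- predict(fit, rbind(c(1, 0), c(0.9, 0), c(1.1, 0)))
  expect_identical(s$labels, c(1L, 1L, 2L))
  expect_equal(s$distances[1], 1)
})

test_that("dimension mismatches and infeasible k are rejected", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(fit_states(x, k = 11, n_replicates = 1, seed = 1), "exceeds")
  expect_error(fit_states(matrix(1, 5, 2), k = 2, n_replicates = 1, seed = 1),
               "distinct")
  fit <- fit_states(x, k = 2, n_replicates = 2, seed = 1)
  expect_error(predict(fit, matrix(0, 3, 5)), "mismatch")
})

test_that("silhouette selection finds well-separated blob counts and matches the direct formula", {
  b <- make_blobs(rbind(c(-4, 0), c(4, 0), c(0, 7)), 20, 0.5, 40)
  sel <- select_k(b$x, k_grid = 2:5, n_replicates = 5, seed = 4)
  expect_identical(sel$best_k, 3L)
  lab3 <- sel$fits[["3"]]$labels
  expect_equal(sel$silhouette_by_k[["3"]], oracle_silhouette(b$x, lab3),
               tolerance = 1e-10)
  # two points, k = 2: all-singleton clustering handled without crash
  expect_warning(
    sel2 <- select_k(rbind(c(0, 0), c(1, 1)), k_grid = 2, n_replicates = 1,
                     seed = 5),
    "singleton")
  expect_identical(unname(sel2$silhouette_by_k), 0)
})

test_that("row order does not change the canonical dictionary", {
  b <- make_blobs(rbind(c(-3, 1, 0), c(3, -1, 0.5), c(0, 4, -2)), 25, 0.4, 50)
  fit1 <- fit_states(b$x, k = 3, n_replicates = 8, seed = 6)
  set.seed(99)
  perm <- sample(nrow(b$x))
  fit2 <- fit_states(b$x[perm, ], k = 3, n_replicates = 8, seed = 6)
  expect_equal(fit1$centroids, fit2$centroids, tolerance = 1e-12)
  expect_identical(fit1$labels[perm], fit2$labels)
})

test_that("centroid matching recovers permutations, sign flips, and a null", {
  set.seed(60)
  a <- matrix(rnorm(5 * 30), 5)
  perm <- c(3, 1, 4, 5, 2)
  m <- match_centroids(a, a[perm, ])
  expect_identical(order(perm), m$mapping$b[order(m$mapping$a)])
  expect_equal(m$mapping$rho, rep(1, 5))
  m2 <- match_centroids(a, -a)
  expect_equal(m2$mapping$rho, rep(-1, 5))
  # independent Gaussian centroids in 861 dimensions are near-orthogonal
  set.seed(61)
  g1 <- matrix(rnorm(5 * 861), 5)
  g2 <- matrix(rnorm(5 * 861), 5)
  m3 <- match_centroids(g1, g2)
  expect_lt(mean(abs(m3$cross_rho)), 0.2)
  # zero-variance centroid is reported missing and left unmatched
  g1[2, ] <- 0.7
  m4 <- match_centroids(g1, g2[1:3, ])
  expect_true(all(is.na(m4$cross_rho[2, ])))
  expect_false(2 %in% m4$mapping$a)
})

test_that("label alignment finds the best pattern permutation", {
  truth <- rep(1:3, each = 10)
  relab <- c(2L, 3L, 1L)[truth]
  relab[1] <- 3L  # one disagreement after alignment
  al <- align_labels(relab, truth, k = 3)
  expect_equal(al$agreement, 29 / 30)
  expect_identical(al$labels[-1], truth[-1])
})

test_that("zero-shift surrogates reproduce the original report exactly", {
  cfg <- toy_config(noise_sd = 0.4, tr = 1)
  ts <- lapply(1:2, function(i)
    make_bold(make_latent_states(cfg, 60, seed = i), cfg, seed = 10 + i,
              subject_id = paste0("s", i)))
  rep0 <- surrogate_control(ts, k = 2, n_replicates = 3, seed = 7,
                            shifts = list(rep(0, 8), rep(0, 8)))
  expect_equal(rep0$coherence_ratio, 1)
  expect_equal(rep0$original$mean_pairwise_l1,
               rep0$surrogate$mean_pairwise_l1)
})
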