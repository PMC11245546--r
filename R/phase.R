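#' ROI time-series container
#'
#' Bundles a T x P matrix of ROI signals (rows = fMRI volumes, columns =
#' regions of interest) with its repetition time and identifiers. This is the
#' input container for the phase-coherence pipeline; one object holds one run.
#'
#' @param data numeric T x P matrix, T >= 3 volumes, P >= 2 ROIs, all finite.
#' @param tr repetition time in seconds (sampling interval of the volumes).
#' @param subject_id subject label.
#' @param run_label run label, conventionally `"rest"`, `"task"` or
#'   `"surrogate"`.
#' @param roi_names optional character vector of P ROI names; defaults to
#'   `roi_001..roi_P`.
#' @return An object of class `roi_ts`: a list with elements `data`, `tr`,
#'   `subject_id`, `run_label`, `roi_names`.
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(300), 100, 3), tr = 1)
#' dim(ts$data)
#' @export
roi_timeseries <- function(data, tr = 1, subject_id = "s01",
                           run_label = "rest", roi_names = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 3L) stop("need at least 3 volumes (rows)")
  if (ncol(data) < 2L) stop("need at least 2 ROIs (columns)")
  if (!all(is.finite(data))) stop("ROI time series contains non-finite values")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a single positive number (seconds)")
  if (is.null(roi_names)) {
    roi_names <- sprintf("roi_%03d", seq_len(ncol(data)))
  }
  if (length(roi_names) != ncol(data))
    stop("'roi_names' length must equal the number of columns")
  structure(
    list(data = data, tr = tr, subject_id = as.character(subject_id),
         run_label = as.character(run_label),
         roi_names = as.character(roi_names)),
    class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject %s, run '%s': %d volumes x %d ROIs, TR = %g s\n",
              x$subject_id, x$run_label, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' @export
as.matrix.roi_ts <- function(x, ...) x$data

# Analytic signal of one real vector via the one-sided spectrum construction:
# double positive frequencies, keep DC (and Nyquist for even n), zero the rest.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    if (n > 2L) h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of ROI signals
#'
#' Converts each ROI signal to its analytic (complex) representation and takes
#' the four-quadrant angle, giving one instantaneous phase per ROI and volume,
#' wrapped to \eqn{[-\pi, \pi]}. Columns are demeaned first by default: a
#' non-zero mean offsets the analytic signal and corrupts the phase.
#'
#' @param ts a [roi_timeseries()] object.
#' @param demean demean each column before the analytic-signal construction
#'   (default `TRUE`). Recorded in the output.
#' @param trim number of volumes to drop from each end of the run after the
#'   transform (default 0, keeping the full volume count). The analytic signal
#'   of a finite record has edge transients; `trim` discards them when exact
#'   volume counts do not matter.
#' @return An object of class `phase_series`: list with `phases` (T x P matrix
#'   in \eqn{[-\pi, \pi]}), `tr`, `subject_id`, `run_label`, `roi_names`,
#'   `demeaned`, `trim`.
#' @examples
#' t <- 0:199
#' ts <- roi_timeseries(cbind(cos(2 * pi * 0.05 * t), sin(2 * pi * 0.05 * t)),
#'                      tr = 1)
#' ph <- instantaneous_phase(ts)
#' range(ph$phases)
#' @export
instantaneous_phase <- function(ts, demean = TRUE, trim = 0L) {
  stopifnot(inherits(ts, "roi_ts"))
  x <- ts$data
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- ts$roi_names[sds == 0]
    stop("constant (zero-variance) ROI column(s): ",
         paste(bad, collapse = ", "), " -- instantaneous phase is undefined")
  }
  if (demean) x <- sweep(x, 2L, colMeans(x))
  ph <- apply(x, 2L, function(col) Arg(analytic_signal(col)))
  trim <- as.integer(trim)
  if (trim > 0L) {
    keep <- seq.int(trim + 1L, nrow(ph) - trim)
    if (length(keep) < 1L) stop("'trim' removes the whole run")
    ph <- ph[keep, , drop = FALSE]
  }
  structure(
    list(phases = ph, tr = ts$tr, subject_id = ts$subject_id,
         run_label = ts$run_label, roi_names = ts$roi_names,
         demeaned = demean, trim = trim),
    class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> subject %s, run '%s': %d volumes x %d ROIs\n",
              x$subject_id, x$run_label, nrow(x$phases), ncol(x$phases)))
  invisible(x)
}

#' Ordered ROI-pair index
#'
#' The fixed pair ordering used throughout: row-major upper triangle, i.e.
#' (1,2), (1,3), ..., (1,P), (2,3), ..., (P-1,P). With P ROIs there are
#' P(P-1)/2 pairs (861 for the 42-ROI parcellation).
#'
#' @param p number of ROIs.
#' @return Integer matrix with columns `i`, `j` (i < j), one row per pair.
#' @examples
#' pair_index(4)
#' @export
pair_index <- function(p) {
  p <- as.integer(p)
  if (p < 2L) stop("'p' must be >= 2")
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- sequence((p - 1L):1L, from = 2L:p)
  cbind(i = i, j = j)
}

#' Per-volume phase-coherence vectors
#'
#' Represents each volume's connectivity configuration as the cosine of the
#' instantaneous phase difference for every ROI pair: +1 for in-phase ROIs,
#' -1 for antiphase. For P ROIs each volume becomes a length P(P-1)/2 vector
#' (861 dimensions for P = 42), using the [pair_index()] ordering.
#'
#' @param ph a [instantaneous_phase()] result.
#' @return An object of class `coherence_series`: list with `vectors`
#'   (T x P(P-1)/2 matrix in \eqn{[-1, 1]}), `pair_index`, `tr`, `subject_id`,
#'   `run_label`, `roi_names`.
#' @examples
#' t <- 0:99
#' ts <- roi_timeseries(cbind(cos(0.3 * t), cos(0.3 * t), -cos(0.3 * t)),
#'                      tr = 1)
#' # identical ROIs cohere at +1, the sign-flipped ROI at -1
#' ch <- coherence_series(instantaneous_phase(ts))
#' colMeans(ch$vectors)
#' @export
coherence_series <- function(ph) {
  stopifnot(inherits(ph, "phase_series"))
  pidx <- pair_index(ncol(ph$phases))
  cth <- cos(ph$phases)
  sth <- sin(ph$phases)
  v <- cth[, pidx[, 1L], drop = FALSE] * cth[, pidx[, 2L], drop = FALSE] +
    sth[, pidx[, 1L], drop = FALSE] * sth[, pidx[, 2L], drop = FALSE]
  v <- pmin(pmax(v, -1), 1)
  structure(
    list(vectors = v, pair_index = pidx, tr = ph$tr,
         subject_id = ph$subject_id, run_label = ph$run_label,
         roi_names = ph$roi_names),
    class = "coherence_series")
}

#' @export
print.coherence_series <- function(x, ...) {
  cat(sprintf(
    "<coherence_series> subject %s, run '%s': %d volumes x %d ROI pairs\n",
    x$subject_id, x$run_label, nrow(x$vectors), nrow(x$pair_index)))
  invisible(x)
}

#' Convert between coherence vectors and symmetric matrices
#'
#' `matrix_from_vector()` rebuilds the symmetric P x P coherence matrix (unit
#' diagonal) from its upper-triangle vectorization; `vector_from_matrix()` is
#' the inverse. The two round-trip bit-exactly.
#'
#' @param v coherence vector of length P(P-1)/2.
#' @param pidx pair index as returned by [pair_index()]; defaults to the
#'   ordering implied by `length(v)`.
#' @return `matrix_from_vector()`: a symmetric P x P matrix with unit
#'   diagonal. `vector_from_matrix()`: a numeric vector.
#' @examples
#' m <- matrix_from_vector(c(0.5, -0.2, 0.1))
#' identical(vector_from_matrix(m), c(0.5, -0.2, 0.1))
#' @export
matrix_from_vector <- function(v, pidx = NULL) {
  d <- length(v)
  p <- (1 + sqrt(1 + 8 * d)) / 2
  if (p != round(p))
    stop("vector length ", d, " is not P(P-1)/2 for any integer P")
  p <- as.integer(round(p))
  if (is.null(pidx)) pidx <- pair_index(p)
  if (nrow(pidx) != d) stop("pair index does not match vector length")
  m <- diag(1, p)
  m[cbind(pidx[, 1L], pidx[, 2L])] <- v
  m[cbind(pidx[, 2L], pidx[, 1L])] <- v
  m
}

#' @rdname matrix_from_vector
#' @param m symmetric square matrix.
#' @export
vector_from_matrix <- function(m, pidx = NULL) {
  p <- nrow(m)
  if (ncol(m) != p) stop("'m' must be square")
  if (is.null(pidx)) pidx <- pair_index(p)
  as.numeric(m[cbind(pidx[, 1L], pidx[, 2L])])
}
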