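# Connectivity stage: instantaneous phases and the phase-lag-index (PLI)
# network.  The PLI between two signals is |< sign(delta_phi(t_k)) >|, the
# absolute time average of the sign of their wrapped phase difference: it is
# 0 when there is no consistent lead/lag (including identical signals) and 1
# when one signal consistently leads the other, regardless of amplitude.

#' Multichannel recording
#'
#' Container for a channels-by-samples numeric matrix plus its sampling rate.
#' Each row is one sensor/channel; columns are time points.
#'
#' @param samples numeric matrix, channels x time points. Arbitrary units.
#' @param sampling_rate sampling frequency in Hz.
#' @param channel_ids optional character vector of channel names; defaults to
#'   `ch001`, `ch002`, ...
#' @return an object of class `recording`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(200), nrow = 2), sampling_rate = 100)
recording <- function(samples, sampling_rate, channel_ids = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stop_param("a recording needs >= 2 channels")
  if (ncol(samples) < 2L) stop_param("a recording needs >= 2 time points")
  if (!all(is.finite(samples))) stop_param("recording samples must be finite")
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0) {
    stop_param("`sampling_rate` must be a positive number (Hz)")
  }
  if (is.null(channel_ids)) {
    channel_ids <- sprintf("ch%03d", seq_len(nrow(samples)))
  }
  if (length(channel_ids) != nrow(samples)) {
    stop_param("`channel_ids` length (%d) does not match channel count (%d)",
               length(channel_ids), nrow(samples))
  }
  rownames(samples) <- channel_ids
  structure(list(channel_ids = as.character(channel_ids),
                 samples = samples,
                 sampling_rate = as.numeric(sampling_rate)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth band-pass forwards and backwards (`signal::filtfilt`)
#' to every channel, so the filter adds no phase distortion — essential when
#' the downstream statistic is a phase-lag measure.
#'
#' @param rec a [recording()].
#' @param low_hz,high_hz band edges in Hz; `0 <= low_hz < high_hz < fs/2`.
#' @param order Butterworth order (default 4).
#' @return a filtered [recording()] of the same shape.
#' @export
band_filter <- function(rec, low_hz, high_hz, order = 4L) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$sampling_rate / 2
  if (!is_scalar_number(low_hz) || !is_scalar_number(high_hz) ||
      low_hz < 0 || low_hz >= high_hz || high_hz >= nyq) {
    stop_param("invalid band: need 0 <= low_hz < high_hz < %g (Nyquist); got [%s, %s]",
               nyq, format(low_hz), format(high_hz))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  filt <- t(apply(rec$samples, 1L, function(x) signal::filtfilt(bf, x)))
  recording(filt, rec$sampling_rate, rec$channel_ids)
}

# Analytic signal via the frequency-domain Hilbert construction: zero the
# negative frequencies, double the positive ones, inverse transform.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of every channel
#'
#' Extracts the analytic-signal (Hilbert) phase of each channel.  Phases lie
#' in `(-pi, pi]`.  A constant (zero-variance) channel has no meaningful
#' phase; it is flagged with a warning and its phases are still returned.
#'
#' @param rec a [recording()].
#' @return an object of class `phase_matrix` with elements `channel_ids` and
#'   `phases` (channels x time points, radians).
#' @export
instantaneous_phase <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  flat <- apply(rec$samples, 1L, stats::var) == 0
  if (any(flat)) {
    warning(sprintf("constant channel(s) with undefined phase: %s",
                    paste(rec$channel_ids[flat], collapse = ", ")),
            call. = FALSE)
  }
  ph <- t(apply(rec$samples, 1L, function(x) Arg(analytic_signal(x))))
  rownames(ph) <- rec$channel_ids
  structure(list(channel_ids = rec$channel_ids, phases = ph,
                 flat_channels = rec$channel_ids[flat]),
            class = "phase_matrix")
}

#' Phase-lag index of one channel pair
#'
#' `pli_pair` computes `| mean_k sign(delta_phi(t_k)) |` where the phase
#' difference is first wrapped into `(-pi, pi]` and `sign(0) = 0`, so
#' identical signals (no consistent lag) score 0 and a constant non-zero lag
#' scores 1.
#'
#' @param phase_a,phase_b numeric phase vectors (radians) of equal length.
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' pli_pair(c(0.2, 0.3, 0.1), c(0, 0, 0.2))  # |(+1 +1 -1)| / 3
pli_pair <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) {
    stop_param("phase vectors differ in length (%d vs %d)",
               length(phase_a), length(phase_b))
  }
  if (length(phase_a) < 1L) stop_param("phase vectors must be non-empty")
  abs(mean(sign(wrap_phase(phase_a - phase_b))))
}

#' Weighted functional-connectivity graph
#'
#' A symmetric non-negative weight matrix over named nodes with a zero
#' diagonal; the container for every network handled by the pipeline.
#'
#' @param weights square numeric matrix with entries in `[0, 1]`.
#' @param node_ids optional node names (defaults to rownames or `n001`...).
#' @return an object of class `connectivity_graph`.
#' @export
connectivity_graph <- function(weights, node_ids = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n != ncol(weights)) stop_param("weight matrix must be square")
  if (!all(is.finite(weights))) stop_param("weights must be finite")
  if (max(abs(weights - t(weights))) > 1e-8) {
    stop_param("weight matrix must be symmetric")
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) stop_param("diagonal must be exactly 0")
  if (min(weights) < 0 || max(weights) > 1) {
    stop_param("off-diagonal weights must lie in [0, 1]")
  }
  if (is.null(node_ids)) node_ids <- rownames(weights)
  if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_len(n))
  if (length(node_ids) != n) stop_param("`node_ids` length mismatch")
  dimnames(weights) <- list(node_ids, node_ids)
  structure(list(node_ids = as.character(node_ids), weights = weights),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<connectivity_graph> %d nodes; edge weights %.3f-%.3f (mean %.3f)\n",
              length(x$node_ids), min(w), max(w), mean(w)))
  invisible(x)
}

# PLI of every pair of rows of a phase matrix; column-sliced loops keep the
# inner arithmetic vectorized over time.
pli_all_pairs <- function(ph) {
  n <- nrow(ph)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    d <- ph[rest, , drop = FALSE] -
      matrix(ph[i, ], length(rest), ncol(ph), byrow = TRUE)
    v <- abs(rowMeans(sign(wrap_phase(d))))
    w[i, rest] <- v
    w[rest, i] <- v
  }
  w
}

#' PLI connectivity matrix from instantaneous phases
#'
#' Builds the dense weighted network whose edge `(i, j)` is the phase-lag
#' index of channels `i` and `j`.  With `epoch_length` set, the recording is
#' cut into consecutive non-overlapping epochs of that many samples, the PLI
#' matrix is computed per epoch and the matrices are averaged; by default one
#' PLI matrix is computed over the whole recording (one network per subject).
#'
#' @param ph a `phase_matrix` from [instantaneous_phase()].
#' @param epoch_length optional epoch length in samples (`NULL` = single
#'   segment).
#' @return a [connectivity_graph()].
#' @export
connectivity_matrix <- function(ph, epoch_length = NULL) {
  stopifnot(inherits(ph, "phase_matrix"))
  n <- nrow(ph$phases)
  if (n < 2L) stop_param("need >= 2 channels")
  if (is.null(epoch_length)) {
    w <- pli_all_pairs(ph$phases)
  } else {
    epoch_length <- check_count(epoch_length, "epoch_length", min = 1L)
    n_ep <- ncol(ph$phases) %/% epoch_length
    if (n_ep < 1L) stop_param("`epoch_length` exceeds the recording length")
    w <- matrix(0, n, n)
    for (e in seq_len(n_ep)) {
      cols <- ((e - 1L) * epoch_length + 1L):(e * epoch_length)
      w <- w + pli_all_pairs(ph$phases[, cols, drop = FALSE])
    }
    w <- w / n_ep
  }
  diag(w) <- 0
  connectivity_graph(w, ph$channel_ids)
}

#' One-call PLI network from a recording
#'
#' Convenience wrapper: optional band-pass, analytic-signal phases, PLI
#' matrix.
#'
#' @param rec a [recording()].
#' @param band optional `c(low_hz, high_hz)` pass band.
#' @param epoch_length see [connectivity_matrix()].
#' @return a [connectivity_graph()].
#' @export
build_network <- function(rec, band = NULL, epoch_length = NULL) {
  if (!is.null(band)) rec <- band_filter(rec, band[1L], band[2L])
  connectivity_matrix(instantaneous_phase(rec), epoch_length = epoch_length)
}
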