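# Synthetic-data module: coupled-oscillator recordings, modular weighted
# graphs, and labeled two-class cohorts with controllable class structure.
# Class differences are encoded in block structure and phase-coupling
# consistency — never in amplitude — because the phase-lag index is
# amplitude-blind; this routes the discriminative signal through the same
# path a real cohort would use.

#' Coupling specification for simulated recordings
#'
#' Channels are partitioned into blocks; each block shares a common sinusoid
#' oscillator (random phase per realization) and every channel mixes that
#' oscillator — shifted by its own phase lag — with independent Gaussian
#' noise.  Distinct per-channel lags make the within-block phase differences
#' consistently non-zero, which is what the PLI detects.
#'
#' @param n_channels total channel count.
#' @param blocks either an integer number of near-equal blocks or a list of
#'   channel-index vectors forming a partition of `1:n_channels`.
#' @param coupling_strength fraction in `[0, 1]` of each channel drawn from
#'   its block oscillator (1 = pure oscillator, 0 = pure noise).
#' @param phase_lags per-channel lags in radians; the default spreads each
#'   block's channels evenly over `(0, pi/2]` so no two coupled channels
#'   share a lag.
#' @param noise_sd standard deviation of the independent noise.
#' @param base_freq_hz oscillator frequency in Hz.
#' @param freq_jitter_hz half-width of the uniform per-block frequency
#'   offset drawn once per realization.  Without it, oscillators of
#'   *different* blocks would share one exact frequency and therefore hold a
#'   constant phase offset — i.e. they would be perfectly phase-locked
#'   despite being uncoupled.  A distinct frequency per block makes
#'   between-block relative phase drift through all angles, so only
#'   within-block pairs show a consistent lag.
#' @return a `coupling_spec` list.
#' @export
coupling_spec <- function(n_channels, blocks = 2L, coupling_strength = 0.9,
                          phase_lags = NULL, noise_sd = 1,
                          base_freq_hz = 10, freq_jitter_hz = 1) {
  n_channels <- check_count(n_channels, "n_channels", min = 2L)
  if (is.numeric(blocks) && length(blocks) == 1L) {
    nb <- check_count(blocks, "blocks")
    if (nb > n_channels) stop_param("more blocks than channels")
    blocks <- split(seq_len(n_channels),
                    rep(seq_len(nb), length.out = n_channels))
  }
  flat <- sort(unlist(blocks, use.names = FALSE))
  if (!identical(flat, seq_len(n_channels))) {
    stop_param("`blocks` must partition 1:%d exactly once", n_channels)
  }
  if (!is_scalar_number(coupling_strength) ||
      coupling_strength < 0 || coupling_strength > 1) {
    stop_param("`coupling_strength` must lie in [0, 1]")
  }
  if (is.null(phase_lags)) {
    phase_lags <- numeric(n_channels)
    for (b in blocks) {
      phase_lags[b] <- (pi / 2) * seq_along(b) / length(b)
    }
  }
  if (length(phase_lags) != n_channels) stop_param("`phase_lags` length mismatch")
  if (!is_scalar_number(noise_sd) || noise_sd <= 0) {
    stop_param("`noise_sd` must be positive")
  }
  if (!is_scalar_number(freq_jitter_hz) || freq_jitter_hz < 0) {
    stop_param("`freq_jitter_hz` must be >= 0")
  }
  structure(list(n_channels = n_channels, blocks = blocks,
                 coupling_strength = coupling_strength,
                 phase_lags = as.numeric(phase_lags),
                 noise_sd = noise_sd, base_freq_hz = base_freq_hz,
                 freq_jitter_hz = freq_jitter_hz),
            class = "coupling_spec")
}

#' Simulate phase-coupled multichannel signals
#'
#' Channel `i` in block `b` is
#' `cs * sin(2*pi*f*t + theta_b + lag_i) + (1 - cs) * noise`, with one random
#' oscillator phase `theta_b` per block and realization.  Uses the current
#' RNG state unless `seed` is given.
#'
#' @param spec a [coupling_spec()].
#' @param n_samples number of time points (>= 2).
#' @param sampling_rate Hz.
#' @param seed optional integer seed (`NULL` = current RNG state).
#' @return a [recording()].
#' @export
simulate_coupled_signals <- function(spec, n_samples, sampling_rate = 250,
                                     seed = NULL) {
  stopifnot(inherits(spec, "coupling_spec"))
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  gen <- function() {
    tt <- (seq_len(n_samples) - 1L) / sampling_rate
    x <- matrix(0, spec$n_channels, n_samples)
    cs <- spec$coupling_strength
    for (b in spec$blocks) {
      theta <- stats::runif(1L, 0, 2 * pi)
      f_b <- spec$base_freq_hz +
        stats::runif(1L, -spec$freq_jitter_hz, spec$freq_jitter_hz)
      for (i in b) {
        x[i, ] <- cs * sin(2 * pi * f_b * tt + theta + spec$phase_lags[i]) +
          (1 - cs) * stats::rnorm(n_samples, sd = spec$noise_sd)
      }
    }
    x
  }
  x <- if (is.null(seed)) gen() else with_seed(seed, gen())
  recording(x, sampling_rate)
}

#' Simulate a modular (planted-block) weighted graph
#'
#' Symmetric weights approximately `w_in` within blocks and `w_out` between
#' blocks, plus symmetric uniform jitter in `[-jitter, jitter]`, clipped to
#' `[0, 1]`, zero diagonal.  With `jitter = 0` the off-diagonal takes exactly
#' two distinct values.
#'
#' @param n_nodes graph order.
#' @param n_blocks number of near-equal planted blocks.
#' @param w_in,w_out within-/between-block weights in `[0, 1]`.
#' @param jitter half-width of the uniform weight jitter.
#' @param seed optional integer seed (`NULL` = current RNG state).
#' @return a [connectivity_graph()] with attribute `blocks` (the planted
#'   block label of every node).
#' @export
simulate_modular_graph <- function(n_nodes, n_blocks, w_in = 0.9,
                                   w_out = 0.1, jitter = 0.05, seed = NULL) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  n_blocks <- check_count(n_blocks, "n_blocks")
  if (n_blocks > n_nodes) stop_param("more blocks than nodes")
  for (w in c(w_in, w_out)) {
    if (!is_scalar_number(w) || w < 0 || w > 1) {
      stop_param("`w_in` and `w_out` must lie in [0, 1]")
    }
  }
  if (!is_scalar_number(jitter) || jitter < 0) stop_param("`jitter` must be >= 0")
  labels <- rep(seq_len(n_blocks), length.out = n_nodes)
  labels <- sort(labels)
  same <- outer(labels, labels, "==")
  w <- ifelse(same, w_in, w_out)
  gen <- function() {
    jit <- matrix(stats::runif(n_nodes^2, -jitter, jitter), n_nodes)
    jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
    pmin(pmax(w + jit, 0), 1)
  }
  if (jitter > 0) w <- if (is.null(seed)) gen() else with_seed(seed, gen())
  diag(w) <- 0
  g <- connectivity_graph(w)
  attr(g, "blocks") <- labels
  g
}

#' Two-class cohort specification
#'
#' @param n_per_class subjects per class.
#' @param class_a,class_b [coupling_spec()] objects for the control and case
#'   classes; must share `n_channels`.
#' @param seed master seed for the cohort.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_class = 20L,
                        class_a = coupling_spec(40L, blocks = 2L),
                        class_b = coupling_spec(40L, blocks = 4L),
                        seed = 1L) {
  stopifnot(inherits(class_a, "coupling_spec"),
            inherits(class_b, "coupling_spec"))
  if (class_a$n_channels != class_b$n_channels) {
    stop_param("both classes must share `n_channels`")
  }
  structure(list(n_per_class = check_count(n_per_class, "n_per_class"),
                 class_a = class_a, class_b = class_b,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "cohort_spec")
}

#' Simulate a labeled two-class cohort of recordings
#'
#' Generates `n_per_class` recordings per class (controls from `class_a`,
#' cases from `class_b`), each with its own derived seed, so the whole
#' cohort is reproducible from the spec's master seed.
#'
#' @param spec a [cohort_spec()].
#' @param n_samples time points per recording.
#' @param sampling_rate Hz.
#' @return list with `recordings` (list of [recording()]), `labels`
#'   (factor, levels control/case), and `subject_ids`.
#' @export
simulate_two_class_cohort <- function(spec, n_samples = 2000L,
                                      sampling_rate = 250) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_class
  labels <- factor(rep(c("control", "case"), each = n),
                   levels = c("control", "case"))
  subject_ids <- sprintf("s%03d", seq_len(2L * n))
  recs <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    cls <- if (i <= n) spec$class_a else spec$class_b
    recs[[i]] <- simulate_coupled_signals(
      cls, n_samples, sampling_rate,
      seed = derive_seed(spec$seed, sprintf("subject-%03d", i)))
  }
  list(recordings = recs, labels = labels, subject_ids = subject_ids)
}
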