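# Connectivity module: band filtering, analytic-signal phase, and the
# phase-lag index.

test_that("band filter passes in-band and attenuates out-of-band tones", {
  rec10 <- sine_recording(c(10, 10), fs = 100, n = 2000)
  f10 <- band_filter(rec10, 8, 12)
  mid <- 500:1500
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(f10$samples[1, mid]) / rms(rec10$samples[1, mid]) - 1),
            0.05)

  rec40 <- sine_recording(c(40, 40), fs = 100, n = 2000)
  f40 <- band_filter(rec40, 8, 12)
  expect_lt(rms(f40$samples[1, mid]) / rms(rec40$samples[1, mid]), 0.10)
})

test_that("band filter rejects invalid bands", {
  rec <- sine_recording(c(5, 5))
  expect_error(band_filter(rec, 12, 8), "invalid band")
  expect_error(band_filter(rec, 8, 60), "invalid band")  # above Nyquist
  expect_error(band_filter(rec, -1, 8), "invalid band")
})

test_that("instantaneous phase advances at the oscillation frequency", {
  # cos(2*pi*5*t) at 100 Hz: phase advances 2*pi*5/100 rad per sample
  fs <- 100; n <- 1000
  tt <- (seq_len(n) - 1) / fs
  rec <- recording(rbind(cos(2 * pi * 5 * tt), cos(2 * pi * 5 * tt)), fs)
  ph <- instantaneous_phase(rec)
  mid <- 200:800
  inc <- diff(ph$phases[1, mid])
  inc <- atan2(sin(inc), cos(inc))
  expect_equal(mean(inc), 2 * pi * 5 / fs, tolerance = 1e-6)
  # identical channels give identical phase rows
  expect_identical(ph$phases[1, ], ph$phases[2, ])
})

test_that("sin and cos of one frequency keep a pi/2 phase offset", {
  fs <- 100; n <- 2000
  tt <- (seq_len(n) - 1) / fs
  rec <- recording(rbind(cos(2 * pi * 8 * tt), sin(2 * pi * 8 * tt)), fs)
  ph <- instantaneous_phase(rec)
  mid <- 500:1500
  d <- ph$phases[1, mid] - ph$phases[2, mid]
  d <- atan2(sin(d), cos(d))
  expect_equal(mean(d), pi / 2, tolerance = 1e-3)
})

test_that("a constant channel is flagged but phases are still returned", {
  rec <- recording(rbind(rep(1, 100), sin(seq_len(100))), 50)
  expect_warning(ph <- instantaneous_phase(rec), "constant channel")
  expect_equal(dim(ph$phases), dim(rec$samples))
  expect_identical(ph$flat_channels, rec$channel_ids[1])
})

test_that("pli_pair matches closed-form cases", {
  n <- 50
  expect_equal(pli_pair(rep(0.3, n), rep(0.3, n)), 0)        # delta = 0
  expect_equal(pli_pair(rep(pi / 3, n), rep(0, n)), 1)       # constant lead
  expect_equal(pli_pair(c(0.2, 0.3, -0.1), c(0, 0, 0)), 1 / 3)
  expect_equal(pli_pair(c(0.2, -0.2, 0.2, -0.2), rep(0, 4)), 0)
  expect_error(pli_pair(1:3, 1:4), "length")
})

test_that("phase differences are wrapped to (-pi, pi] before the signum", {
  # +3*pi/2 must behave as -pi/2
  expect_equal(pli_pair(rep(3 * pi / 2, 10), rep(0, 10)),
               pli_pair(rep(-pi / 2, 10), rep(0, 10)))
  # mixed wrapped signs cancel
  expect_equal(pli_pair(c(3 * pi / 2, pi / 2), c(0, 0)), 0)
})

test_that("pli_pair is symmetric and common-offset invariant", {
  withr::with_seed(42, {
    for (i in 1:20) {
      a <- stats::runif(30, -pi, pi)
      b <- stats::runif(30, -pi, pi)
      off <- stats::runif(1, -10, 10)
      expect_equal(pli_pair(a, b), pli_pair(b, a))
      expect_equal(pli_pair(a + off, b + off), pli_pair(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("pli_pair equals a brute-force sign loop on random short inputs", {
  brute_pli <- function(a, b) {
    s <- 0
    for (k in seq_along(a)) {
      d <- a[k] - b[k]
      while (d > pi) d <- d - 2 * pi
      while (d <= -pi) d <- d + 2 * pi
      s <- s + sign(d)
    }
    abs(s) / length(a)
  }
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- sample(1:32, 1)
      a <- stats::runif(n, -3 * pi, 3 * pi)
      b <- stats::runif(n, -3 * pi, 3 * pi)
      expect_equal(pli_pair(a, b), brute_pli(a, b), tolerance = 1e-12)
    }
  })
})

test_that("connectivity matrices are symmetric, zero-diagonal, in [0,1]", {
  withr::with_seed(99, {
    for (i in 1:5) {
      nch <- sample(3:8, 1)
      rec <- recording(matrix(stats::rnorm(nch * 300), nch), 100)
      g <- connectivity_matrix(instantaneous_phase(rec))
      expect_identical(g$weights, t(g$weights))
      expect_true(all(diag(g$weights) == 0))
      expect_gte(min(g$weights), 0)
      expect_lte(max(g$weights), 1)
    }
  })
})

test_that("identical channels yield zero PLI weight", {
  tt <- seq_len(500) / 100
  x <- sin(2 * pi * 7 * tt)
  rec <- recording(rbind(x, x), 100)
  g <- connectivity_matrix(instantaneous_phase(rec))
  expect_equal(g$weights[1, 2], 0)
})

test_that("independent uniform phases give near-zero PLI", {
  ph <- withr::with_seed(123, structure(
    list(channel_ids = c("a", "b", "c"),
         phases = matrix(stats::runif(3 * 10000, -pi, pi), 3)),
    class = "phase_matrix"))
  g <- connectivity_matrix(ph)
  off <- g$weights[upper.tri(g$weights)]
  expect_true(all(off < 0.05))
})

test_that("epoch-averaged PLI averages the per-epoch matrices", {
  withr::with_seed(5, {
    ph <- structure(list(channel_ids = c("a", "b", "c"),
                         phases = matrix(stats::runif(3 * 400, -pi, pi), 3)),
                    class = "phase_matrix")
  })
  g_all <- connectivity_matrix(ph, epoch_length = 200)
  g1 <- connectivity_matrix(
    structure(list(channel_ids = ph$channel_ids,
                   phases = ph$phases[, 1:200]), class = "phase_matrix"))
  g2 <- connectivity_matrix(
    structure(list(channel_ids = ph$channel_ids,
                   phases = ph$phases[, 201:400]), class = "phase_matrix"))
  expect_equal(g_all$weights, (g1$weights + g2$weights) / 2, tolerance = 1e-12)
})

test_that("connectivity_graph enforces its invariants", {
  expect_error(connectivity_graph(matrix(1:6, 2, 3)), "square")
  w <- matrix(c(0, 0.5, 0.4, 0), 2, 2)
  expect_error(connectivity_graph(w), "symmetric")
  w <- matrix(c(0.1, 0.5, 0.5, 0), 2, 2)
  expect_error(connectivity_graph(w), "diagonal")
  w <- matrix(c(0, 1.5, 1.5, 0), 2, 2)
  expect_error(connectivity_graph(w), "\\[0, 1\\]")
})
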