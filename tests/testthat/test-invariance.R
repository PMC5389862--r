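test_that("waveform distance matches direct arithmetic on random vectors", {
  set.seed(14)
  for (i in 1:100) {
    x <- stats::rnorm(30); y <- stats::rnorm(30)
    expect_equal(trace_distance(x, y), oracle_distance(x, y),
                 tolerance = 1e-12)
  }
  # hand-evaluated toy: msd = 2/3, larger half-range = 1/2
  expect_equal(trace_distance(c(0, 1, 0), c(0, 0, 1)), (2 / 3) / 0.25,
               tolerance = 1e-12)
})

test_that("waveform distance is zero under identity and additive shifts", {
  x <- sin(seq(0, 6, by = 0.01))
  expect_equal(trace_distance(x, x), 0)
  expect_equal(trace_distance(x, x + 5), 0, tolerance = 1e-12)
  expect_warning(res <- trace_distance(rep(1, 10), rep(2, 10)), "constant")
  expect_true(is.na(res))
  # scale invariance of the normalized form
  y <- cos(seq(0, 6, by = 0.01))
  expect_equal(trace_distance(3 * x, 3 * y), trace_distance(x, y),
               tolerance = 1e-12)
})

test_that("stimulus detectability is zero for the beat itself and falls with f", {
  spec2 <- quick_spec(f_beat = 2, phase = 0)
  w2 <- insert_chirp(spec2)
  b2 <- make_beat(spec2)
  self <- b2; self$chirp_onset <- spec2$chirp_onset
  expect_equal(stimulus_detectability(self, b2), 0, tolerance = 1e-12)
  # phase-averaged detectability at 2 Hz exceeds 64 Hz
  pa <- function(f) {
    b <- make_beat(quick_spec(f_beat = f))
    mean(vapply(phase_grid(quick_spec(f_beat = f)), function(s)
      stimulus_detectability(insert_chirp(s), b), numeric(1)))
  }
  expect_gt(pa(2), pa(64))
  # oracle recomputation at (2 Hz, phase 0)
  on <- spec2$chirp_onset
  sel <- w2$times >= on & w2$times <= on + 0.5
  expect_equal(stimulus_detectability(w2, b2),
               oracle_distance(w2$values[sel], b2$values[sel]),
               tolerance = 1e-9)
  expect_error(stimulus_detectability(b2, b2), "no chirp")
})

test_that("inter-chirp distance averages the 28 phase pairs", {
  g <- phase_grid(quick_spec(f_beat = 8))
  ws <- lapply(g, insert_chirp)
  expect_equal(ncol(utils::combn(8, 2)), 28)
  d <- inter_chirp_distance(ws)
  expect_gt(d, 0)
  # identical copies give zero
  expect_equal(inter_chirp_distance(list(ws[[1]], ws[[1]], ws[[1]])), 0,
               tolerance = 1e-12)
  expect_error(inter_chirp_distance(ws[1]), "at least 2")
})

test_that("neural detectability follows the max-min contrast ratio", {
  expect_equal(neuronal_detectability(3, 1), 0.5)
  expect_equal(neuronal_detectability(1, 3), 0.5)        # symmetric
  expect_equal(neuronal_detectability(2, 2), 0)
  expect_equal(neuronal_detectability(5, 0), 1)
  expect_warning(res <- neuronal_detectability(0, 0), "zero")
  expect_true(is.na(res))
  set.seed(3)
  for (i in 1:50) {
    r <- stats::runif(2, 0, 10)
    v <- neuronal_detectability(r[1], r[2])
    expect_true(v >= 0 && v <= 1)
    expect_equal(v, neuronal_detectability(r[2], r[1]))
  }
  # trace interface
  tr1 <- structure(list(times = seq(0, 1, 0.01), values = sin(seq(0, 1, 0.01) * 20)),
                   class = "response_trace")
  tr2 <- structure(list(times = seq(0, 1, 0.01), values = rep(0.5, 101)),
                   class = "response_trace")
  expect_equal(neuronal_detectability(tr1, tr2, c(0, 1), c(0, 1)), 1)
})

test_that("invariance score hits its two anchor points", {
  tau <- seq(0, 0.1, by = 0.001)
  stimuli <- lapply(seq(0, 315, 45), function(p)
    list(times = tau, values = sin(2 * pi * 10 * tau + p * pi / 180)))
  same <- lapply(1:8, function(i) list(times = tau, values = cos(40 * tau)))
  expect_equal(invariance_score(same, stimuli, 0.1), 1)
  expect_equal(invariance_score(stimuli, stimuli, 0.1), 0)
  expect_warning(res <- invariance_score(same, same, 0.1), "stimulus distance")
  expect_true(is.na(res))
  expect_error(invariance_score(same[1:3], stimuli, 0.1), "match")
})

test_that("response duration finds a known perturbation and skips null ones", {
  at <- seq(0, 3, by = 0.001)
  set.seed(6)
  noise <- stats::rnorm(length(at), 0, 0.05)
  beat <- structure(list(times = at, values = noise), class = "response_trace")
  resp <- beat
  bump <- at >= 1 & at < 1.3
  resp$values <- resp$values + ifelse(bump, 1, 0)
  d <- response_duration(resp, beat, onset = 1, smooth = 0.05)
  expect_equal(d, 0.3, tolerance = 0.12)
  # identical traces: no suprathreshold interval
  expect_true(is.na(response_duration(beat, beat, onset = 1)))
})

test_that("power-law exponent recovers from noisy synthetic durations", {
  f <- c(1, 2, 4, 8, 16, 32, 64, 128)
  set.seed(99)
  d <- 0.05 * f^-0.8 * (1 + stats::rnorm(8, 0, 0.02))
  fit <- fit_duration_powerlaw(d, f)
  expect_lt(abs(fit$b - (-0.8)), 0.05)
  expect_gt(fit$r_squared, 0.98)
  expect_equal(predict(fit, 4), fit$a * 4^fit$b)
  expect_error(fit_duration_powerlaw(c(0.1, NA, NA, 0.2), f[1:4]), ">= 3")
})
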