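test_that("zero stimulus drives the baseline rate everywhere", {
  am <- make_beat(beat_spec(2, 1))
  am$values <- am$values * 0
  r <- rate_from_am(am, afferent_params())
  expect_true(all(r$values == afferent_params()$baseline_rate))
})

test_that("default calibration rectifies at 64 Hz but not at <= 10 Hz", {
  p <- afferent_params()
  for (f in c(1, 2, 4, 8, 10)) {
    r <- rate_from_am(make_beat(quick_spec(f_beat = f)), p)
    expect_true(all(r$values > 0), label = paste("no rectification at", f, "Hz"))
  }
  r64 <- rate_from_am(make_beat(quick_spec(f_beat = 64)), p)
  expect_true(any(r64$values == 0))
  expect_gt(mean(r64$values == 0), 0.25)  # silent fraction anchor
})

test_that("silent fraction matches the arcsin closed form within 1%", {
  p <- afferent_params()
  spec <- beat_spec(64, 1)  # 64 full cycles
  r <- rate_from_am(make_beat(spec), p)
  A <- p$gain_at_1Hz * 64^p$gain_exponent * spec$contrast
  analytic <- 0.5 - asin(p$baseline_rate / A) / pi     # rectified-sinusoid arc
  expect_equal(mean(r$values == 0), analytic, tolerance = 0.01)
  expect_equal(silent_fraction(p$baseline_rate, A), analytic, tolerance = 1e-12)
  expect_equal(silent_fraction(300, 100), 0)           # subthreshold drive
})

test_that("Poisson sampling recovers rate and Fano factor", {
  tr <- sample_spikes(flat_rate(100), poisson_params(100))
  counts <- vapply(tr$trains, length, numeric(1))
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 100))  # 3 SE
  tr500 <- sample_spikes(flat_rate(100), poisson_params(500, seed = 7))
  c500 <- vapply(tr500$trains, length, numeric(1))
  expect_equal(stats::var(c500) / mean(c500), 1, tolerance = 0.1)
  # zero rate gives empty trains
  empty <- sample_spikes(flat_rate(0), poisson_params(5))
  expect_true(all(vapply(empty$trains, length, numeric(1)) == 0))
})

test_that("gamma-renewal sampling is rate-correct and sub-Poisson", {
  p <- afferent_params(isi_shape = 8, latency = 0, noise_seed = 11,
                       n_trials = 300)
  tr <- sample_spikes(flat_rate(100), p)
  counts <- vapply(tr$trains, length, numeric(1))
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 8 / 300) + 1)
  expect_lt(stats::var(counts) / mean(counts), 0.3)  # Fano ~ 1/8
  # spike times strictly increasing and inside the trial
  expect_true(all(vapply(tr$trains, function(s)
    all(diff(s) > 0) && all(s >= 0 & s < tr$duration), logical(1))))
})

test_that("identical seeds give identical spike trains", {
  r <- rate_from_am(make_beat(quick_spec(f_beat = 8)), afferent_params())
  a <- sample_spikes(r, afferent_params(noise_seed = 42, n_trials = 10))
  b <- sample_spikes(r, afferent_params(noise_seed = 42, n_trials = 10))
  expect_identical(a$trains, b$trains)
})

test_that("axonal latency delays every spike", {
  # rate pulse confined to [0.2, 0.3] s
  rt <- flat_rate(0, duration = 1)
  rt$values[rt$times >= 0.2 & rt$times < 0.3] <- 500
  tr <- sample_spikes(rt, afferent_params(latency = 0.009, isi_shape = 1,
                                          noise_seed = 2, n_trials = 20))
  st <- unlist(tr$trains)
  expect_true(all(st >= 0.2 + 0.009 - 2e-3))  # rate ramps over one grid step
  expect_true(all(st <= 0.3 + 0.009 + 1e-3))
})

test_that("population simulation produces shared-drive correlations", {
  expect_error(make_population(make_beat(quick_spec()), list(afferent_params())),
               "2 afferents")
  spec <- quick_spec(f_beat = 2, phase = 0)
  am <- insert_chirp(spec)
  # zero gain: no shared drive, correlation indistinguishable from zero
  p0 <- lapply(1:2, function(k)
    afferent_params(gain_at_1Hz = 0, noise_seed = k, n_trials = 150))
  pop0 <- make_population(am, p0)
  rho0 <- sliding_correlation(pop0[[1]], pop0[[2]], 2,
                              t_start = 0.2, t_end = 1.2)
  expect_lt(abs(mean(rho0$values, na.rm = TRUE)), 2 / sqrt(5 * 150))
  # default gain at 2 Hz: correlation rises after chirp onset
  pd <- lapply(1:2, function(k)
    afferent_params(noise_seed = k + 10, n_trials = 150))
  popd <- make_population(am, pd)
  on <- spec$chirp_onset
  rhod <- sliding_correlation(popd[[1]], popd[[2]], 2,
                              t_start = on - 0.5, t_end = on + 0.5)
  sh <- shift_response(rhod, 0.009)
  pre <- mean(sh$values[sh$times < on], na.rm = TRUE)
  post <- mean(sh$values[sh$times >= on & sh$times < on + 0.1], na.rm = TRUE)
  expect_gt(post, pre)
  # identical seeds and params: correlation 1 wherever defined
  pid <- lapply(1:2, function(k) afferent_params(noise_seed = 5, n_trials = 20))
  popi <- make_population(am, pid)
  expect_identical(popi[[1]]$trains, popi[[2]]$trains)
  rhoi <- sliding_correlation(popi[[1]], popi[[2]], 2,
                              t_start = on, t_end = on + 0.2)
  expect_true(all(abs(rhoi$values[!is.na(rhoi$values)] - 1) < 1e-12))
})

test_that("phase locking is non-decreasing in beat frequency", {
  plis <- vapply(c(2, 8, 32, 64, 128), function(f) {
    p <- afferent_params(noise_seed = 3, n_trials = 60)
    tr <- sample_spikes(rate_from_am(make_beat(beat_spec(f, 1)), p), p)
    shifted <- lapply(tr$trains, function(s) s - p$latency)
    phase_locking_index(phase_histogram(shifted, f))
  }, numeric(1))
  expect_false(is.unsorted(plis))
  expect_equal(plis[1], 0)   # no silent phases at 2 Hz
  expect_gt(plis[4], 0)      # rectification visible at 64 Hz
})

test_that("baseline rate and silent fraction recover from spikes at 500 trials", {
  p <- afferent_params(noise_seed = 9, n_trials = 500)
  # baseline recovery on an unmodulated epoch
  tr <- sample_spikes(flat_rate(p$baseline_rate, duration = 0.5),
                      afferent_params(noise_seed = 9, n_trials = 500,
                                      latency = 0))
  est <- mean(vapply(tr$trains, length, numeric(1))) / 0.5
  expect_equal(est, p$baseline_rate, tolerance = 0.05)
  # silent-fraction recovery from binarized counts at 64 Hz
  spec <- beat_spec(64, 0.5)
  r <- rate_from_am(make_beat(spec), p)
  trains <- sample_spikes(r, p)
  shifted <- lapply(trains$trains, function(s) s - p$latency)
  hist <- phase_histogram(shifted, 64, n_bins = 80)
  emp <- sum(hist$counts == 0) / hist$n_bins
  A <- p$gain_at_1Hz * 64^p$gain_exponent * spec$contrast
  # 80-bin quantization biases the empirical arc down by at most 2 bins
  expect_lt(abs(emp - silent_fraction(p$baseline_rate, A)), 0.05)
})
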