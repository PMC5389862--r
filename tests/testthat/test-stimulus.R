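test_that("beat synthesis has the right period, amplitude, and periodicity", {
  spec <- beat_spec(2, 1)
  b <- make_beat(spec)
  # exactly 2 full AM cycles in 1 s at 2 Hz: value repeats at lag 1/f
  lag <- round(spec$sample_rate / spec$f_beat)
  expect_equal(b$values[seq_len(lag)], b$values[lag + seq_len(lag)],
               tolerance = 1e-12)
  expect_gt(stats::cor(b$values[seq_len(lag)], b$values[lag + seq_len(lag)]),
            0.999)
  # default contrast from the recordings' average stimulus intensity
  expect_equal(max(b$values), 0.34, tolerance = 1e-6)
  expect_lte(max(abs(b$values)), spec$contrast * (1 + 1e-12))
})

test_that("beat AM matches the envelope of an explicit two-carrier sum", {
  f1 <- 1000; f_beat <- 2; a <- 0.02; sr <- 1e5; dur <- 1
  t <- (seq_len(dur * sr) - 1) / sr
  carrier <- sin(2 * pi * f1 * t) + a * sin(2 * pi * (f1 - f_beat) * t)
  # rectify-and-low-pass envelope: sqrt(2 x mean power) over 20 carrier cycles
  # (an integer cycle count, so the 2 f1 component cancels exactly)
  k <- round(sr / f1) * 20
  sm <- as.numeric(stats::filter(carrier^2, rep(1 / k, k), sides = 2))
  # compare over exactly one full beat cycle so the DC subtraction is exact
  keep <- !is.na(sm) & t >= 0.25 & t < 0.75
  env <- sqrt(2 * sm[keep])
  am_extracted <- env - mean(env)
  # the synthesized AM, phase-aligned (envelope is cosine-phased)
  ref <- a * cos(2 * pi * f_beat * t[keep])
  expect_lt(sqrt(mean((am_extracted - ref)^2)) / sqrt(mean(ref^2)), 0.01)
})

test_that("chirp profile peaks at delta_f with the documented width", {
  p <- make_chirp_profile(60, 0.014, 10000)
  expect_equal(max(p$excursion), 60, tolerance = 1e-9)
  expect_equal(p$sigma * 4, 0.014)          # duration = +/- 2 sigma width
  expect_equal(p$excursion[1], 0)           # zero at the window edges
  expect_equal(p$excursion[length(p$excursion)], 0)
  expect_true(all(p$excursion >= 0))
  # zero-excursion chirp is identically zero
  expect_true(all(make_chirp_profile(0, 0.014)$excursion == 0))
  expect_error(make_chirp_profile(60, -1), "delta_t")
})

test_that("numerical profile area matches the closed form within 0.1%", {
  for (dt_s in c(0.014, 0.02, 0.05)) {
    p <- make_chirp_profile(60, dt_s, 50000)
    h <- diff(p$times[1:2])
    num <- sum((p$excursion[-1] + p$excursion[-length(p$excursion)]) / 2) * h
    expect_equal(num, chirp_profile_area(60, dt_s), tolerance = 1e-3)
  }
})

test_that("insert_chirp reduces to make_beat when delta_f = 0, bitwise", {
  spec <- quick_spec(f_beat = 4, phase = 90, delta_f = 0)
  expect_identical(insert_chirp(spec)$values, make_beat(spec)$values)
})

test_that("chirp phase-advances the beat by the excursion integral", {
  spec <- quick_spec(f_beat = 2, phase = 45)
  w <- insert_chirp(spec)
  b <- make_beat(spec)
  # independent oracle: trapezoidal integral of the sampled profile
  p <- make_chirp_profile(spec$delta_f, spec$delta_t, spec$sample_rate)
  h <- diff(p$times[1:2])
  adv_cycles <- sum((p$excursion[-1] + p$excursion[-length(p$excursion)]) / 2) * h
  post <- w$times > spec$chirp_onset + spec$delta_t
  expected <- spec$contrast *
    sin(2 * pi * spec$f_beat * w$times[post] + 2 * pi * adv_cycles)
  expect_equal(w$values[post], expected, tolerance = 1e-6)
  # pre-onset the waveform equals the plain beat exactly
  pre <- w$times < spec$chirp_onset
  expect_identical(w$values[pre], b$values[pre])
})

test_that("the chirp perturbation is causal", {
  spec <- quick_spec(f_beat = 8, phase = 135)
  d <- insert_chirp(spec)$values - make_beat(spec)$values
  dt <- 1 / spec$sample_rate
  expect_true(all(d[spec_t <- insert_chirp(spec)$times < spec$chirp_onset - dt] == 0))
  expect_gt(sum(d^2), 0)
})

test_that("chirp windows at mirror phases are time-reversed sign mirrors", {
  f <- 2; W <- 0.014
  spec1 <- quick_spec(f_beat = f, phase = 45)
  adv <- chirp_profile_area(spec1$delta_f, W)
  psi <- (-45 - 360 * f * W - 360 * adv) %% 360
  spec2 <- quick_spec(f_beat = f, phase = psi)
  w1 <- insert_chirp(spec1); w2 <- insert_chirp(spec2)
  tau <- seq(0, W, by = 1 / spec1$sample_rate)
  v1 <- stats::approx(w1$times - spec1$chirp_onset, w1$values, tau)$y
  v2 <- stats::approx(w2$times - spec2$chirp_onset, w2$values, tau)$y
  expect_equal(-rev(v1), v2, tolerance = 1e-3)
})

test_that("phase_grid returns the standard 8 phases sharing one grid", {
  g <- phase_grid(quick_spec(f_beat = 16))
  expect_length(g, 8)
  expect_equal(vapply(g, function(s) s$chirp_phase, numeric(1)),
               seq(0, 315, by = 45))
  expect_length(unique(vapply(g, function(s) s$total_duration, numeric(1))), 1)
  # pre-chirp segments all equal the plain beat
  b <- make_beat(g[[1]])
  for (s in g) {
    w <- insert_chirp(s)
    pre <- w$times < s$chirp_onset
    expect_identical(w$values[pre], b$values[pre])
  }
})

test_that("invalid stimulus parameters are rejected by name", {
  expect_error(stimulus_spec(f_beat = -1), "f_beat")
  expect_error(stimulus_spec(delta_t = 0), "delta_t")
  expect_error(stimulus_spec(contrast = 0), "contrast")
  expect_error(stimulus_spec(sample_rate = 100), "sample_rate")
  expect_error(stimulus_spec(f_beat = 2, chirp_phase = 0, total_duration = 0.5),
               "total_duration")
  # phase reduced modulo 360
  expect_equal(stimulus_spec(chirp_phase = 405)$chirp_phase, 45)
})
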