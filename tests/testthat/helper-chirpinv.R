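# shared builders for small, fast fixtures

quick_spec <- function(f_beat = 2, phase = 0, ...) {
  stimulus_spec(f_beat = f_beat, chirp_phase = phase, ...)
}

# beat-only spec with a freely chosen (possibly short) duration
beat_spec <- function(f_beat, duration, ...) {
  stimulus_spec(f_beat = f_beat, chirp_phase = 0, n_cycles_before = 0,
                total_duration = duration, ...)
}

# paper-style 2-decimal rounding (half away from zero, not half to even)
round2 <- function(x) floor(x * 100 + 0.5) / 100

# a bare rate trace on a uniform grid
flat_rate <- function(rate_hz, duration = 1, sr = 1000) {
  n <- round(duration * sr)
  structure(list(times = (seq_len(n) - 1) / sr,
                 values = rep(rate_hz, n)),
            class = "rate_trace")
}

# Poisson afferent with no axonal delay, for rate-recovery checks
poisson_params <- function(n_trials, seed = 1, ...) {
  afferent_params(isi_shape = 1, latency = 0, noise_seed = seed,
                  n_trials = n_trials, ...)
}

# direct (brute-force) implementation of the normalized waveform distance
oracle_distance <- function(x, y) {
  num <- mean(((x - mean(x)) - (y - mean(y)))^2)
  den <- max((max(x) - min(x)) / 2, (max(y) - min(y)) / 2)
  num / den^2
}

# brute-force windowed spike-count correlation at one window position
oracle_rho <- function(trains_i, trains_j, t0, Tw, n_bins = 5) {
  count_bins <- function(st) {
    edges <- t0 + Tw * (0:n_bins) / n_bins
    vapply(seq_len(n_bins), function(b)
      sum(st >= edges[b] & st < edges[b + 1]), numeric(1))
  }
  x <- unlist(lapply(trains_i$trains, count_bins))
  y <- unlist(lapply(trains_j$trains, count_bins))
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cov(x, y) / sqrt(stats::var(x) * stats::var(y))
}
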