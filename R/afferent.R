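#' Parameters of the P-unit-like afferent model
#'
#' The model afferent fires at a baseline rate modulated linearly by the AM
#' through a high-pass, power-law gain `g(f) = gain_at_1Hz * f^gain_exponent`
#' evaluated at the instantaneous modulation frequency, with half-wave
#' rectification at zero rate. The default calibration is anchored to two
#' constraints: no rectification for beat frequencies up to 10 Hz at the
#' default contrast, and a silent fraction above 25% of the beat cycle at
#' 64 Hz.
#'
#' @param baseline_rate Baseline firing rate in the absence of stimulation,
#'   Hz.
#' @param gain_at_1Hz Rate gain at 1 Hz modulation frequency,
#'   (spikes/s)/(mV/cm).
#' @param gain_exponent High-pass power-law slope of gain vs. modulation
#'   frequency (dimensionless).
#' @param latency Axonal transmission delay added to every spike time, s
#'   (default 9 ms; the analysis compensates it with [shift_response()]).
#' @param isi_shape Gamma order of the interspike-interval distribution in
#'   operational (rate-rescaled) time. 1 gives an inhomogeneous Poisson
#'   process; larger values give the more regular, sub-Poisson firing
#'   characteristic of P-units (count Fano factor about `1/isi_shape`),
#'   without which shot noise swamps the stimulus-driven count correlations
#'   in the short high-beat-frequency windows. Default 8.
#' @param noise_seed Integer seed; the same seed yields identical spike
#'   trains.
#' @param n_trials Number of stimulus repetitions to simulate.
#' @return An object of class `afferent_params`.
#' @export
afferent_params <- function(baseline_rate = 300, gain_at_1Hz = 320,
                            gain_exponent = 0.35, latency = 0.009,
                            isi_shape = 8, noise_seed = 1L,
                            n_trials = 200L) {
  stopifnot(baseline_rate > 0, gain_at_1Hz >= 0, gain_exponent >= 0,
            latency >= 0, isi_shape >= 1, n_trials >= 1)
  structure(list(baseline_rate = baseline_rate, gain_at_1Hz = gain_at_1Hz,
                 gain_exponent = gain_exponent, latency = latency,
                 isi_shape = isi_shape, noise_seed = as.integer(noise_seed),
                 n_trials = as.integer(n_trials)),
            class = "afferent_params")
}

afferent_gain <- function(params, f) params$gain_at_1Hz * f^params$gain_exponent

#' Instantaneous firing rate driven by an AM waveform
#'
#' `r(t) = max(0, baseline_rate + g(f_inst) * AM(t))`. The gain is evaluated
#' at the beat frequency during the beat epochs and at the delta_f-dominated
#' effective chirp frequency (`f_beat + delta_f`) inside the chirp window, so
#' chirp responses are strong at all beat frequencies while rectification
#' during the beat appears only once the modulated term exceeds baseline.
#'
#' @param am An `am_waveform`.
#' @param params An [afferent_params()].
#' @return A list of class `rate_trace` with `times` (s) and `values` (Hz) on
#'   the AM's grid.
#' @export
rate_from_am <- function(am, params) {
  stopifnot(inherits(am, "am_waveform"), inherits(params, "afferent_params"))
  spec <- am$spec
  g <- rep(afferent_gain(params, spec$f_beat), length(am$times))
  if (!is.null(am$chirp_onset) && spec$delta_f > 0) {
    inside <- am$times >= am$chirp_onset &
      am$times <= am$chirp_onset + spec$delta_t
    g[inside] <- afferent_gain(params, spec$f_beat + spec$delta_f)
  }
  r <- pmax(0, params$baseline_rate + g * am$values)
  structure(list(times = am$times, values = r), class = "rate_trace")
}

#' Silent fraction of a rectified sinusoidal rate
#'
#' Closed-form fraction of the beat cycle over which
#' `baseline + A sin(theta)` is negative (zero after rectification):
#' `1/2 - asin(baseline/A)/pi` for `A > baseline`, else 0.
#'
#' @param baseline_rate Baseline rate, Hz.
#' @param modulation_amplitude Peak rate modulation `A = g(f) * contrast`, Hz.
#' @return Fraction of the cycle in (0, 1/2), or 0 if no rectification.
#' @export
silent_fraction <- function(baseline_rate, modulation_amplitude) {
  if (modulation_amplitude <= baseline_rate) return(0)
  0.5 - asin(baseline_rate / modulation_amplitude) / pi
}

#' Bundle per-trial spike-time vectors
#'
#' Container used by the simulator and accepted by every neural metric; use
#' it to analyse user-supplied event data in place of simulated trains.
#'
#' @param trains List of numeric vectors of spike times (s), one per trial,
#'   each strictly increasing within `[0, duration)`.
#' @param duration Trial duration, s.
#' @return An object of class `spike_trains`.
#' @export
spike_trains <- function(trains, duration) {
  structure(list(trains = trains, duration = duration,
                 n_trials = length(trains)),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  n <- vapply(x$trains, length, integer(1))
  cat("Spike trains:", x$n_trials, "trials over", signif(x$duration, 4),
      "s; mean rate", signif(mean(n) / x$duration, 4), "Hz\n")
  invisible(x)
}

#' Sample spike trains from a rate trace
#'
#' With `isi_shape = 1`, inhomogeneous-Poisson generation by thinning:
#' homogeneous candidates at the peak rate are accepted with probability
#' `r(t)/r_max` (linear interpolation of the rate trace). With
#' `isi_shape > 1`, time-rescaled gamma-renewal generation: interspike
#' intervals in operational time `Lambda(t) = integral of r` are drawn from
#' a Gamma(`isi_shape`, `isi_shape`) distribution (unit mean) and mapped
#' back through the inverse of `Lambda`, yielding regular, sub-Poisson
#' firing. In both cases spikes are then delayed by the afferent's axonal
#' `latency` (spikes shifted past the trial end are dropped). Reproducible
#' under `params$noise_seed`.
#'
#' @param rate A `rate_trace` from [rate_from_am()] (values >= 0).
#' @param params An [afferent_params()]; `n_trials` independent trials are
#'   drawn.
#' @return A `spike_trains` object: a list of strictly increasing spike-time
#'   vectors, one per trial, plus the trial duration.
#' @export
sample_spikes <- function(rate, params) {
  stopifnot(inherits(rate, "rate_trace"), all(rate$values >= 0))
  duration <- rate$times[length(rate$times)] + diff(rate$times[1:2])
  rmax <- max(rate$values)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$noise_seed)
  shape <- if (is.null(params$isi_shape)) 1 else params$isi_shape
  dt <- diff(rate$times[1:2])
  if (shape > 1) {
    # operational time, made strictly increasing so silent (r = 0) stretches
    # still invert cleanly
    Lam <- cumtrapz(rate$values, dt) + seq_along(rate$times) * 1e-12
    total <- Lam[length(Lam)]
  }
  trains <- vector("list", params$n_trials)
  for (k in seq_len(params$n_trials)) {
    if (rmax <= 0) { trains[[k]] <- numeric(0); next }
    if (shape > 1) {
      n_draw <- ceiling(total + 4 * sqrt(total / shape) + 10)
      s <- cumsum(stats::rgamma(n_draw, shape = shape, rate = shape))
      s <- s[s < total]
      st <- stats::approx(Lam, rate$times, s, rule = 2)$y + params$latency
    } else {
      n_cand <- stats::rpois(1, rmax * duration)
      tc <- sort(stats::runif(n_cand, 0, duration))
      r_at <- stats::approx(rate$times, rate$values, tc, rule = 2)$y
      st <- tc[stats::runif(n_cand) < r_at / rmax] + params$latency
    }
    trains[[k]] <- st[st < duration]
  }
  spike_trains(trains, duration)
}

#' Simulate a population of afferents driven by a shared stimulus
#'
#' All afferents see the same AM (the shared-stimulus drive that induces
#' pairwise spike-count correlations) but draw independent private spiking
#' noise via their own seeds.
#'
#' @param am An `am_waveform`.
#' @param params_list List of [afferent_params()], one per afferent; at least
#'   two are required for pairwise analyses.
#' @return A list of `spike_trains`, one element per afferent.
#' @export
make_population <- function(am, params_list) {
  if (length(params_list) < 2L)
    stop("configuration error: at least 2 afferents are required for ",
         "pairwise correlation analyses")
  lapply(params_list, function(p) sample_spikes(rate_from_am(am, p), p))
}
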