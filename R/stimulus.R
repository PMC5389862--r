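#' Stimulus specification for a beat with an optional embedded chirp
#'
#' Describes the sinusoidal amplitude modulation (AM, the "beat") that arises
#' from the interference of two electric organ discharges, plus an optional
#' small (type II) chirp: a brief, unimodal excursion of the emitter's EOD
#' frequency that transiently accelerates, and thereby phase-advances, the
#' beat.
#'
#' Beat phase 0 degrees is defined at the upward zero-crossing of the AM;
#' `chirp_phase` is the beat phase at chirp onset, i.e. at the start of the
#' excursion window. The chirp is scheduled after `n_cycles_before` full beat
#' cycles, so an unperturbed reference epoch always precedes it.
#'
#' @param f_beat Beat frequency in Hz (difference of the two EOD frequencies).
#' @param chirp_phase Beat phase at chirp onset, degrees; reduced modulo 360.
#' @param delta_f Peak EOD-frequency excursion of the chirp, Hz.
#' @param delta_t Chirp duration in seconds, defined as the full width of the
#'   excursion window (+/- 2 sigma of the underlying Gaussian profile).
#' @param contrast AM amplitude in mV/cm.
#' @param sample_rate Sampling rate in Hz.
#' @param n_cycles_before Number of full beat cycles before the chirp.
#' @param total_duration Total stimulus duration in seconds. Defaults to at
#'   least one second and at least one full beat cycle after the chirp, and is
#'   independent of `chirp_phase` so that all phase variants at one beat
#'   frequency share a common time grid.
#' @return An object of class `stimulus_spec`.
#' @examples
#' spec <- stimulus_spec(f_beat = 2)
#' spec$total_duration
#' @export
stimulus_spec <- function(f_beat = 2, chirp_phase = 0, delta_f = 60,
                          delta_t = 0.014, contrast = 0.34,
                          sample_rate = 10000, n_cycles_before = 2,
                          total_duration = NULL) {
  if (!is.numeric(f_beat) || length(f_beat) != 1L || f_beat <= 0)
    stop("invalid stimulus parameter 'f_beat': must be a single value > 0")
  if (!is.numeric(delta_t) || length(delta_t) != 1L || delta_t <= 0)
    stop("invalid stimulus parameter 'delta_t': must be a single value > 0")
  if (!is.numeric(delta_f) || length(delta_f) != 1L || delta_f < 0)
    stop("invalid stimulus parameter 'delta_f': must be a single value >= 0")
  if (!is.numeric(contrast) || length(contrast) != 1L || contrast <= 0)
    stop("invalid stimulus parameter 'contrast': must be a single value > 0")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      sample_rate < 20 / delta_t)
    stop("invalid stimulus parameter 'sample_rate': must be >= 20/delta_t ",
         "so the chirp is resolvable")
  if (!is.numeric(chirp_phase) || length(chirp_phase) != 1L)
    stop("invalid stimulus parameter 'chirp_phase': must be a single number")
  chirp_phase <- chirp_phase %% 360
  if (n_cycles_before < 0)
    stop("invalid stimulus parameter 'n_cycles_before': must be >= 0")

  # onset time realizing the requested beat phase after n_cycles_before cycles
  chirp_onset <- (n_cycles_before + chirp_phase / 360) / f_beat
  if (is.null(total_duration)) {
    # phase-independent default: room for the latest grid phase (315 deg) plus
    # the chirp and one full beat cycle after it, never less than 1 s
    latest_onset <- (n_cycles_before + 315 / 360) / f_beat
    total_duration <- max(1, latest_onset + delta_t + 2 / f_beat)
  }
  if (chirp_onset + delta_t > total_duration)
    stop("invalid stimulus parameter 'total_duration': chirp scheduled ",
         "outside [0, total_duration]")

  structure(list(f_beat = f_beat, chirp_phase = chirp_phase,
                 delta_f = delta_f, delta_t = delta_t, contrast = contrast,
                 sample_rate = sample_rate, n_cycles_before = n_cycles_before,
                 total_duration = total_duration, chirp_onset = chirp_onset),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("Stimulus spec: beat", x$f_beat, "Hz, contrast", x$contrast, "mV/cm\n")
  if (x$delta_f > 0)
    cat("  chirp: delta_f", x$delta_f, "Hz, delta_t", x$delta_t * 1000,
        "ms, phase", x$chirp_phase, "deg, onset", signif(x$chirp_onset, 4),
        "s\n")
  cat("  duration", signif(x$total_duration, 4), "s at", x$sample_rate,
      "Hz\n")
  invisible(x)
}

am_waveform <- function(times, values, spec, chirp_onset = NULL) {
  structure(list(times = times, values = values, spec = spec,
                 chirp_onset = chirp_onset),
            class = "am_waveform")
}

#' @export
print.am_waveform <- function(x, ...) {
  cat("AM waveform:", length(x$times), "samples,",
      signif(x$spec$total_duration, 4), "s, beat", x$spec$f_beat, "Hz",
      if (!is.null(x$chirp_onset))
        paste(", chirp onset", signif(x$chirp_onset, 4), "s") else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.am_waveform <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time (s)",
                 ylab = "AM (mV/cm)", ...)
  if (!is.null(x$chirp_onset))
    graphics::abline(v = x$chirp_onset, col = "red", lty = 2)
  invisible(x)
}

spec_times <- function(spec) {
  n <- round(spec$total_duration * spec$sample_rate)
  (seq_len(n) - 1L) / spec$sample_rate
}

#' Generate a beat amplitude modulation
#'
#' Synthesizes the sinusoidal AM directly in the envelope domain:
#' `AM(t) = contrast * sin(2 pi f_beat t)`, with phase zero (an upward
#' zero-crossing) at `t = 0`. Chirp fields of the spec are ignored.
#'
#' @param spec A [stimulus_spec()].
#' @return An `am_waveform` (fields `times`, `values`, `spec`).
#' @examples
#' b <- make_beat(stimulus_spec(f_beat = 2, total_duration = 1))
#' max(b$values)
#' @export
make_beat <- function(spec) {
  if (!inherits(spec, "stimulus_spec")) stop("'spec' must be a stimulus_spec")
  t <- spec_times(spec)
  am_waveform(t, spec$contrast * sin(2 * pi * spec$f_beat * t), spec)
}

#' Chirp frequency-excursion profile
#'
#' The emitter's EOD-frequency excursion during a small chirp, modelled as a
#' truncated Gaussian: a `sigma = delta_t/4` Gaussian restricted to its
#' +/- 2 sigma window and rescaled so it is exactly zero at the window edges
#' and peaks at `delta_f` in the middle. Times are relative to chirp onset.
#'
#' @param delta_f Peak excursion, Hz (>= 0).
#' @param delta_t Duration (full +/- 2 sigma width), s.
#' @param sample_rate Sampling rate, Hz.
#' @return A list of class `chirp_profile` with `times` (s, from 0 to
#'   `delta_t`) and `excursion` (Hz).
#' @export
make_chirp_profile <- function(delta_f, delta_t, sample_rate = 10000) {
  if (delta_t <= 0) stop("invalid parameter 'delta_t': must be > 0")
  if (delta_f < 0) stop("invalid parameter 'delta_f': must be >= 0")
  t <- seq(0, delta_t, by = 1 / sample_rate)
  sigma <- delta_t / 4
  tc <- delta_t / 2
  raw <- exp(-(t - tc)^2 / (2 * sigma^2))
  edge <- exp(-2)                     # value of the Gaussian at +/- 2 sigma
  exc <- delta_f * pmax(0, raw - edge) / (1 - edge)
  structure(list(times = t, excursion = exc, delta_f = delta_f,
                 delta_t = delta_t, sigma = sigma),
            class = "chirp_profile")
}

#' Analytic area of the chirp excursion profile
#'
#' Closed-form time integral (Hz * s, i.e. cycles of accumulated phase
#' advance) of the truncated-Gaussian profile used by [make_chirp_profile()].
#'
#' @inheritParams make_chirp_profile
#' @return Integral of the excursion over the chirp window, in cycles.
#' @export
chirp_profile_area <- function(delta_f, delta_t) {
  sigma <- delta_t / 4
  edge <- exp(-2)
  gauss_area <- sigma * sqrt(2 * pi) * (2 * stats::pnorm(2) - 1)
  delta_f * (gauss_area - 4 * sigma * edge) / (1 - edge)
}

# excursion evaluated on the full stimulus grid (zero outside the chirp)
excursion_on_grid <- function(spec, times) {
  exc <- numeric(length(times))
  if (spec$delta_f <= 0) return(exc)
  sigma <- spec$delta_t / 4
  tc <- spec$chirp_onset + spec$delta_t / 2
  inside <- times >= spec$chirp_onset & times <= spec$chirp_onset + spec$delta_t
  edge <- exp(-2)
  exc[inside] <- spec$delta_f *
    pmax(0, exp(-(times[inside] - tc)^2 / (2 * sigma^2)) - edge) / (1 - edge)
  exc
}

cumtrapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(numeric(n))
  c(0, cumsum((y[-1] + y[-n]) / 2) * dt)
}

#' Embed a chirp in a beat
#'
#' Generates the AM a receiver fish senses when the emitter produces a small
#' chirp: the instantaneous AM frequency is `f_beat + excursion(t)`, so the
#' waveform equals the plain beat before chirp onset and is phase-advanced by
#' `2 pi * integral(excursion)` afterwards (the "phase reset" of the beat).
#'
#' @param spec A [stimulus_spec()] with the chirp fields set.
#' @return An `am_waveform` with `chirp_onset` set.
#' @examples
#' w <- insert_chirp(stimulus_spec(f_beat = 16, chirp_phase = 90))
#' w$chirp_onset
#' @export
insert_chirp <- function(spec) {
  if (!inherits(spec, "stimulus_spec")) stop("'spec' must be a stimulus_spec")
  t <- spec_times(spec)
  exc <- excursion_on_grid(spec, t)
  phase <- 2 * pi * spec$f_beat * t + 2 * pi * cumtrapz(exc, 1 / spec$sample_rate)
  am_waveform(t, spec$contrast * sin(phase), spec, chirp_onset = spec$chirp_onset)
}

#' The 8-phase stimulus grid
#'
#' Variants of one spec with chirp phases 0, 45, ..., 315 degrees.
#'
#' @param spec A [stimulus_spec()]; its `chirp_phase` is replaced.
#' @param phases Phases in degrees (default the standard 45-degree grid).
#' @return A list of `stimulus_spec` objects differing only in `chirp_phase`
#'   (and hence chirp onset time); all share the same `total_duration`.
#' @export
phase_grid <- function(spec, phases = seq(0, 315, by = 45)) {
  lapply(phases, function(p)
    stimulus_spec(f_beat = spec$f_beat, chirp_phase = p,
                  delta_f = spec$delta_f, delta_t = spec$delta_t,
                  contrast = spec$contrast, sample_rate = spec$sample_rate,
                  n_cycles_before = spec$n_cycles_before,
                  total_duration = spec$total_duration))
}
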