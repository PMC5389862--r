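# window extraction on a trace; traces are (times, values) lists
trace_segment <- function(trace, t_start, t_end) {
  sel <- trace$times >= t_start - 1e-12 & trace$times <= t_end + 1e-12
  list(times = trace$times[sel], values = trace$values[sel])
}

# resample a trace's values onto a reference time grid (linear)
resample_values <- function(trace, at) {
  ok <- is.finite(trace$values)
  if (sum(ok) < 2L) return(rep(NA_real_, length(at)))
  stats::approx(trace$times[ok], trace$values[ok], at, rule = 2)$y
}

#' Normalized distance between two waveforms
#'
#' The mean squared difference of the mean-subtracted traces over an analysis
#' window, normalized by the square of the larger half peak-to-peak range:
#' `D(x, y) = <(x - <x> - y + <y>)^2> / max((max(x)-min(x))/2,
#' (max(y)-min(y))/2)^2`. The normalization makes D dimensionless and
#' invariant to a common rescaling, so distances between firing-rate traces,
#' correlation time courses, and stimulus waveforms live on one scale.
#' `D(x, x) = 0`, and additive constants cancel. If both traces are constant
#' over the window the distance is undefined and `NA` is returned with a
#' warning.
#'
#' @param x,y Numeric vectors on a common grid, or `response_trace` /
#'   `am_waveform`-like lists with `times` and `values`.
#' @param window `c(start, end)` in seconds; required for trace input,
#'   ignored for plain vectors. When grids differ, `y` is resampled onto
#'   `x`'s grid.
#' @return Dimensionless distance >= 0, or `NA_real_` if undefined.
#' @export
trace_distance <- function(x, y, window = NULL) {
  if (is.numeric(x) && is.numeric(y)) {
    xv <- x; yv <- y
    if (length(xv) != length(yv)) stop("input error: vectors differ in length")
  } else {
    if (is.null(window)) stop("'window' is required for trace input")
    xs <- trace_segment(x, window[1], window[2])
    if (length(xs$times) < 2L) stop("input error: window contains < 2 samples")
    xv <- xs$values
    yv <- resample_values(y, xs$times)
  }
  ok <- is.finite(xv) & is.finite(yv)
  if (sum(ok) < 2L) return(NA_real_)
  xv <- xv[ok]; yv <- yv[ok]
  half_range <- max((max(xv) - min(xv)) / 2, (max(yv) - min(yv)) / 2)
  if (half_range == 0) {
    warning("distance undefined: both traces constant over the window")
    return(NA_real_)
  }
  mean(((xv - mean(xv)) - (yv - mean(yv)))^2) / half_range^2
}

#' Stimulus-level detectability of a chirp
#'
#' Distance between the chirp-bearing AM and the phase-matched unperturbed
#' beat over one full beat cycle starting at chirp onset. Zero means the
#' chirp waveform is indistinguishable from the beat.
#'
#' @param chirp_am `am_waveform` with an embedded chirp.
#' @param beat_am The corresponding beat-only `am_waveform` on the same grid.
#' @return Dimensionless detectability >= 0.
#' @export
stimulus_detectability <- function(chirp_am, beat_am) {
  if (is.null(chirp_am$chirp_onset)) stop("input error: no chirp in 'chirp_am'")
  if (length(chirp_am$times) != length(beat_am$times) ||
      any(abs(chirp_am$times[1:2] - beat_am$times[1:2]) > 1e-12))
    stop("input error: mismatched time grids")
  onset <- chirp_am$chirp_onset
  f <- chirp_am$spec$f_beat
  trace_distance(chirp_am, beat_am, window = c(onset, onset + 1 / f))
}

#' Mean pairwise distance between phase variants of a chirp
#'
#' Distance between the chirp waveforms occurring at different beat phases,
#' aligned to chirp onset, averaged over all unordered pairs (28 pairs for
#' the 8-phase grid). The analysis window is the chirp duration (14 ms by
#' default) after onset.
#'
#' @param waveforms List of >= 2 `am_waveform`s with chirps, one per phase.
#' @param window_length Window after chirp onset, s (default 0.014).
#' @return Mean pairwise dimensionless distance.
#' @export
inter_chirp_distance <- function(waveforms, window_length = 0.014) {
  if (length(waveforms) < 2L) stop("input error: need at least 2 waveforms")
  aligned <- lapply(waveforms, function(w) {
    if (is.null(w$chirp_onset)) stop("input error: waveform without chirp")
    list(times = w$times - w$chirp_onset, values = w$values)
  })
  tau <- seq(0, window_length, by = 1 / waveforms[[1]]$spec$sample_rate)
  vals <- lapply(aligned, resample_values, at = tau)
  pairs <- utils::combn(length(vals), 2)
  mean(apply(pairs, 2, function(p) trace_distance(vals[[p[1]]], vals[[p[2]]])))
}

#' Max-minus-min response range within a window
#'
#' @param trace A `response_trace` (PSTH or correlation trace).
#' @param window `c(start, end)` in seconds on the trace's axis.
#' @return `max - min` of the (defined) values in the window.
#' @export
response_range <- function(trace, window) {
  seg <- trace_segment(trace, window[1], window[2])
  v <- seg$values[is.finite(seg$values)]
  if (length(v) == 0L) return(NA_real_)
  max(v) - min(v)
}

#' Neural detectability index
#'
#' `|R_chirp - R_beat| / (R_chirp + R_beat)` where each R is the
#' max-minus-min response range: of the chirp response in a window sized by
#' the fitted response duration, and of the undisturbed-beat response over
#' one beat cycle. Applies identically to PSTHs and correlation traces.
#' Always in `[0, 1]` for nonnegative ranges and symmetric in its arguments;
#' undefined (NA, with a warning) when both ranges are zero.
#'
#' @param r_chirp,r_beat Nonnegative scalar response ranges, or
#'   `response_trace`s (then `chirp_window` and `beat_window` select the
#'   ranges).
#' @param chirp_window,beat_window `c(start, end)` windows used when traces
#'   are supplied.
#' @return Detectability in `[0, 1]`, or `NA_real_`.
#' @export
neuronal_detectability <- function(r_chirp, r_beat, chirp_window = NULL,
                                   beat_window = NULL) {
  if (!is.numeric(r_chirp)) r_chirp <- response_range(r_chirp, chirp_window)
  if (!is.numeric(r_beat)) r_beat <- response_range(r_beat, beat_window)
  if (is.na(r_chirp) || is.na(r_beat)) return(NA_real_)
  if (r_chirp < 0 || r_beat < 0) stop("response ranges must be >= 0")
  if (r_chirp + r_beat == 0) {
    warning("neuronal detectability undefined: both response ranges are zero")
    return(NA_real_)
  }
  abs((r_chirp - r_beat) / (r_chirp + r_beat))
}

# mean pairwise distance among a set of onset-aligned traces over [0, window]
pairwise_mean_distance <- function(traces, window, grid_n = NULL) {
  tau0 <- traces[[1]]$times
  tau <- tau0[tau0 >= -1e-12 & tau0 <= window + 1e-12]
  if (length(tau) < 2L)
    tau <- seq(0, window, length.out = if (is.null(grid_n)) 50 else grid_n)
  vals <- lapply(traces, resample_values, at = tau)
  pairs <- utils::combn(length(vals), 2)
  ds <- apply(pairs, 2, function(p) trace_distance(vals[[p[1]]], vals[[p[2]]]))
  mean(ds, na.rm = TRUE)
}

#' Phase-invariance score
#'
#' `I = 1 - mean pairwise D(responses) / mean pairwise D(stimuli)`, clipped
#' to `[0, 1]`. Responses and stimulus waveforms are both aligned to chirp
#' onset (time 0) and compared over `[0, window]`. The score is 1 when the
#' responses to the chirp at all beat phases are identical despite distinct
#' stimulus waveforms, and about 0 when the responses differ as much as the
#' stimulus waveforms themselves do.
#'
#' @param responses List of onset-aligned `response_trace`s (or any
#'   `times`/`values` lists), one per beat phase.
#' @param stimuli List of onset-aligned stimulus waveforms, one per phase.
#' @param window Analysis window length after onset, s (from the matching
#'   response-duration power-law fit for neural scores; 1 s for behavior).
#' @return Invariance score in `[0, 1]`, or `NA_real_` if the stimulus
#'   distance is undefined or zero.
#' @export
invariance_score <- function(responses, stimuli, window) {
  if (length(responses) != length(stimuli))
    stop("input error: responses and stimuli must match in length")
  if (length(responses) < 2L) stop("input error: need >= 2 phase conditions")
  d_resp <- pairwise_mean_distance(responses, window)
  d_stim <- pairwise_mean_distance(stimuli, window)
  if (!is.finite(d_stim) || d_stim == 0) {
    warning("invariance undefined: zero or undefined mean stimulus distance")
    return(NA_real_)
  }
  if (!is.finite(d_resp)) return(NA_real_)
  min(1, max(0, 1 - d_resp / d_stim))
}

#' Duration of the chirp-evoked response
#'
#' Length of the first contiguous post-onset interval over which the absolute
#' difference between the chirp response and the phase-matched
#' undisturbed-beat response exceeds its beat-epoch (pre-onset) level by `k`
#' standard deviations (threshold = baseline mean + `k` baseline SD, since
#' the absolute difference is a folded-noise level with nonzero mean).
#' Because the raw difference between two oscillating responses passes
#' through zero within the response, the criterion is applied to its
#' envelope: the absolute difference is boxcar-smoothed over `smooth` seconds
#' (half a beat period in the standard pipeline) before thresholding, with
#' the baseline statistics taken from the same smoothed trace.
#'
#' @param resp_chirp,resp_beat `response_trace`s on a common absolute time
#'   axis (PSTHs or correlation traces).
#' @param onset Chirp onset on that axis, s.
#' @param baseline_window `c(start, end)` of the beat epoch used for the
#'   residual SD; defaults to everything before onset.
#' @param k Threshold in baseline SDs (default 2).
#' @param smooth Boxcar length (s) applied to the absolute difference;
#'   0 disables smoothing.
#' @return Duration in seconds, or `NA_real_` if no suprathreshold interval
#'   exists (e.g. identical traces).
#' @export
response_duration <- function(resp_chirp, resp_beat, onset,
                              baseline_window = NULL, k = 2, smooth = 0) {
  at <- resp_chirp$times
  d <- abs(resp_chirp$values - resample_values(resp_beat, at))
  if (smooth > 0) {
    d[!is.finite(d)] <- 0
    d <- smooth_boxcar(d, round(smooth / stats::median(diff(at))))
  }
  if (is.null(baseline_window)) baseline_window <- c(min(at), onset)
  base <- d[at >= baseline_window[1] & at < baseline_window[2]]
  base <- base[is.finite(base)]
  if (length(base) < 2L) stop("input error: baseline window too short")
  thr <- mean(base) + k * stats::sd(base)
  post <- which(at >= onset)
  above <- d[post] > thr
  above[is.na(above)] <- FALSE
  if (!any(above)) return(NA_real_)
  first <- which(above)[1]
  run_len <- which(!above[first:length(above)])[1] - 1L
  if (is.na(run_len)) run_len <- length(above) - first + 1L
  run_len * stats::median(diff(at))
}

# reference for the duration measure: the undisturbed-beat response carrying
# the chirp's permanent phase reset, i.e. advanced by `advance_s` seconds
# after the chirp window, so the post-transient difference decays instead of
# persisting at the phase-offset amplitude forever
phase_advanced_reference <- function(beat_trace, onset, chirp_len, advance_s) {
  at <- beat_trace$times
  out <- beat_trace
  post <- at >= onset + chirp_len
  if (any(post))
    out$values[post] <- resample_values(beat_trace, at[post] + advance_s)
  out
}

#' Power-law fit of response duration vs. beat frequency
#'
#' Least-squares fit of `d = a * f^b` in log-log coordinates; frequencies
#' with undefined durations are excluded.
#'
#' @param durations Response durations, s (one per frequency; `NA` allowed).
#' @param f_beat Matching beat frequencies, Hz.
#' @return Object of class `duration_fit`: `a`, `b` (exponent), `r_squared`,
#'   and the retained `durations`/`f_beat`.
#' @export
fit_duration_powerlaw <- function(durations, f_beat) {
  ok <- is.finite(durations) & durations > 0 & is.finite(f_beat)
  if (sum(ok) < 3L) stop("input error: need >= 3 defined durations to fit")
  fit <- stats::lm(log(durations[ok]) ~ log(f_beat[ok]))
  structure(list(a = unname(exp(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 r_squared = summary(fit)$r.squared,
                 durations = durations[ok], f_beat = f_beat[ok]),
            class = "duration_fit")
}

#' @export
print.duration_fit <- function(x, ...) {
  cat("Power-law fit d = a * f^b: a =", signif(x$a, 4), "s, b =",
      signif(x$b, 3), ", R^2 =", signif(x$r_squared, 3), "(",
      length(x$durations), "frequencies )\n")
  invisible(x)
}

#' @param object A `duration_fit`.
#' @param f_beat Frequencies (Hz) at which to evaluate the fitted duration.
#' @param ... Unused.
#' @return Predicted durations in seconds.
#' @rdname fit_duration_powerlaw
#' @export
predict.duration_fit <- function(object, f_beat, ...) {
  object$a * f_beat^object$b
}
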