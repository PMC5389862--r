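#' @keywords internal
response_trace <- function(times, values, kind = "rate") {
  structure(list(times = times, values = values, kind = kind),
            class = "response_trace")
}

#' @export
print.response_trace <- function(x, ...) {
  cat("Response trace (", x$kind, "): ", length(x$times), " samples, t in [",
      signif(min(x$times), 4), ", ", signif(max(x$times), 4), "] s\n",
      sep = "")
  invisible(x)
}

#' @export
plot.response_trace <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time (s)",
                 ylab = x$kind, ...)
  invisible(x)
}

# spike-time input normalization: numeric vector or spike_trains
as_train_list <- function(trains) {
  if (inherits(trains, "spike_trains")) return(trains$trains)
  if (is.numeric(trains)) return(list(trains))
  if (is.list(trains)) return(trains)
  stop("expected spike times, a list of spike-time vectors, or spike_trains")
}

#' Bin a spike train into a binary sequence
#'
#' Counts spikes in half-open bins `[k w, (k+1) w)`; a spike at time `t`
#' lands in bin `floor(t/w) + 1`. Bins may hold more than one spike.
#'
#' @param train Numeric vector of spike times (s).
#' @param binwidth Bin width in seconds (default 0.5 ms).
#' @param duration Total duration covered (s); defaults to just past the last
#'   spike.
#' @return Object of class `binary_sequence`: integer `counts`, `binwidth`.
#' @export
binarize <- function(train, binwidth = 0.0005, duration = NULL) {
  if (binwidth <= 0) stop("'binwidth' must be > 0")
  if (is.null(duration))
    duration <- if (length(train)) max(train) + binwidth else binwidth
  n_bins <- max(1L, ceiling(duration / binwidth - 1e-9))
  idx <- floor(train / binwidth) + 1
  idx <- idx[idx >= 1 & idx <= n_bins]
  structure(list(counts = tabulate(idx, n_bins), binwidth = binwidth),
            class = "binary_sequence")
}

# boxcar smoothing with reflect padding; kernel length forced odd
smooth_boxcar <- function(x, width_bins) {
  k <- max(1L, as.integer(width_bins))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < 2L) return(x)
  h <- (k - 1L) %/% 2L
  h <- min(h, length(x) - 1L)
  k <- 2L * h + 1L
  padded <- c(rev(x[seq_len(h)]), x, rev(x[seq.int(length(x) - h + 1L, length(x))]))
  sm <- stats::filter(padded, rep(1 / k, k), sides = 2)
  as.numeric(sm[seq.int(h + 1L, h + length(x))])
}

#' Peristimulus time histogram
#'
#' Trial-averaged firing rate with boxcar smoothing (reflect padding at the
#' edges, which conserves the spike-count integral for responses supported
#' away from the trace boundaries).
#'
#' @param trains `spike_trains`, or a list of spike-time vectors.
#' @param binwidth PSTH bin width, s (default 0.1 ms).
#' @param smooth_width Boxcar filter length, s (default 6 ms).
#' @param duration Duration covered, s; taken from `spike_trains` if absent.
#' @return A `response_trace` with bin-center `times` and `values` in Hz.
#' @export
psth <- function(trains, binwidth = 0.0001, smooth_width = 0.006,
                 duration = NULL) {
  tl <- as_train_list(trains)
  if (length(tl) == 0L) stop("input error: empty trial set")
  if (is.null(duration)) {
    if (inherits(trains, "spike_trains")) duration <- trains$duration
    else duration <- max(c(0, unlist(tl))) + binwidth
  }
  n_bins <- max(1L, ceiling(duration / binwidth - 1e-9))
  counts <- numeric(n_bins)
  for (tr in tl) {
    idx <- floor(tr / binwidth) + 1
    idx <- idx[idx >= 1 & idx <= n_bins]
    counts <- counts + tabulate(idx, n_bins)
  }
  rate <- counts / (length(tl) * binwidth)
  rate <- smooth_boxcar(rate, round(smooth_width / binwidth))
  response_trace((seq_len(n_bins) - 0.5) * binwidth, rate, kind = "rate")
}

#' Phase histogram of beat-epoch spikes
#'
#' Maps each spike to its beat phase `(2 pi f_beat t + phase0) mod 2 pi` and
#' bins over one cycle.
#'
#' @param train Spike times (s), a list of them, or `spike_trains`; trials
#'   are pooled.
#' @param f_beat Beat frequency, Hz (> 0).
#' @param phase0 Phase at `t = 0`, radians (default 0: the package's beat
#'   convention).
#' @param n_bins Number of phase bins (default 20).
#' @param t_range Optional `c(start, end)` restricting spikes to the beat
#'   epoch; errors if no spikes-eligible epoch remains.
#' @return Object of class `phase_histogram`: `counts`, `n_bins`,
#'   `breaks` (radians).
#' @export
phase_histogram <- function(train, f_beat, phase0 = 0, n_bins = 20,
                            t_range = NULL) {
  if (f_beat <= 0) stop("'f_beat' must be > 0")
  if (n_bins < 2) stop("'n_bins' must be >= 2")
  spikes <- unlist(as_train_list(train))
  if (!is.null(t_range)) {
    if (diff(t_range) <= 0) stop("input error: empty beat epoch")
    spikes <- spikes[spikes >= t_range[1] & spikes < t_range[2]]
  }
  ph <- (2 * pi * f_beat * spikes + phase0) %% (2 * pi)
  idx <- pmin(floor(ph / (2 * pi / n_bins)) + 1, n_bins)
  structure(list(counts = tabulate(idx, n_bins), n_bins = n_bins,
                 breaks = seq(0, 2 * pi, length.out = n_bins + 1)),
            class = "phase_histogram")
}

#' Phase-locking index
#'
#' Fraction of phase-histogram bins whose count falls below a threshold of
#' `threshold_factor` times the mean bin count (0.05% by default, which with
#' count data flags exactly-silent bins). Zero means spikes occur at all beat
#' phases; the index approaches `(n_bins - 1)/n_bins` as all spikes
#' concentrate in a single phase bin. An all-zero histogram is undefined and
#' returns `NA`.
#'
#' @param hist A `phase_histogram`.
#' @param threshold_factor Multiplier on the mean bin count (default 5e-4).
#' @return Index in `[0, (n_bins - 1)/n_bins]`, or `NA_real_` if undefined.
#' @export
phase_locking_index <- function(hist, threshold_factor = 5e-4) {
  stopifnot(inherits(hist, "phase_histogram"))
  if (sum(hist$counts) == 0) {
    warning("phase-locking index undefined: all-zero phase histogram")
    return(NA_real_)
  }
  thr <- threshold_factor * mean(hist$counts)
  sum(hist$counts < thr) / hist$n_bins
}

#' Shift a response trace earlier in time
#'
#' Advances the time axis by `delay` to compensate for axonal transmission
#' delay (default 9 ms). Applied to neural traces only, never to stimulus or
#' behavioral traces.
#'
#' @param trace A `response_trace` (or any list with a `times` field).
#' @param delay Delay in seconds, >= 0.
#' @return The trace with `times - delay`.
#' @export
shift_response <- function(trace, delay = 0.009) {
  if (delay < 0) stop("'delay' must be >= 0")
  span <- diff(range(trace$times))
  if (delay > span) stop("input error: delay exceeds trace length")
  trace$times <- trace$times - delay
  trace
}
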