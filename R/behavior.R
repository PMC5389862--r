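#' Parameters of the echo-chirp behavior generator
#'
#' Echo responses are modelled as a driven inhomogeneous point process: a low
#' baseline chirp-emission rate plus, after each stimulus chirp, a transient
#' Gaussian rate bump (latency-jittered) whose integrated area is
#' `echo_gain * drive`, where the drive in `[0, 1]` is supplied per stimulus
#' condition (by default the correlation-based neural detectability).
#'
#' @param baseline_rate Spontaneous chirp-emission rate, chirps/s.
#' @param echo_gain Expected emitted chirps per stimulus chirp at drive 1.
#' @param latency_mean,latency_sd Echo latency distribution, s.
#' @param n_trials Trials per stimulus condition.
#' @param seed Integer seed; identical seeds give identical series.
#' @return Object of class `echo_params`.
#' @export
echo_params <- function(baseline_rate = 0.05, echo_gain = 1.5,
                        latency_mean = 0.25, latency_sd = 0.08,
                        n_trials = 500L, seed = 1L) {
  stopifnot(baseline_rate >= 0, echo_gain >= 0, latency_sd > 0, n_trials >= 1)
  structure(list(baseline_rate = baseline_rate, echo_gain = echo_gain,
                 latency_mean = latency_mean, latency_sd = latency_sd,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "echo_params")
}

#' Simulate behavioral echo-chirp series
#'
#' @param stimulus_times Stimulus chirp onset times within a trial, s.
#' @param trial_duration Trial length, s.
#' @param drive Detectability drive in `[0, 1]` scaling the echo bump.
#' @param params An [echo_params()].
#' @param f_beat,phase Condition labels carried on the output.
#' @return Object of class `echo_series`: `trials` (list of emitted chirp
#'   time vectors), `stimulus_times`, `trial_duration`, labels, `params`.
#' @export
simulate_echoes <- function(stimulus_times, trial_duration, drive, params,
                            f_beat = NA_real_, phase = NA_real_) {
  stopifnot(inherits(params, "echo_params"), drive >= 0, drive <= 1,
            all(stimulus_times >= 0), all(stimulus_times <= trial_duration))
  peak_bump <- params$echo_gain * drive / (params$latency_sd * sqrt(2 * pi))
  rmax <- params$baseline_rate + peak_bump * length(stimulus_times)
  rate_at <- function(t) {
    r <- rep(params$baseline_rate, length(t))
    for (s in stimulus_times)
      r <- r + params$echo_gain * drive *
        stats::dnorm(t, s + params$latency_mean, params$latency_sd)
    r
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)
  trials <- vector("list", params$n_trials)
  for (k in seq_len(params$n_trials)) {
    if (rmax <= 0) { trials[[k]] <- numeric(0); next }
    n_cand <- stats::rpois(1, rmax * trial_duration)
    tc <- sort(stats::runif(n_cand, 0, trial_duration))
    trials[[k]] <- tc[stats::runif(n_cand) < rate_at(tc) / rmax]
  }
  structure(list(trials = trials, stimulus_times = stimulus_times,
                 trial_duration = trial_duration, f_beat = f_beat,
                 phase = phase, params = params),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  n <- vapply(x$trials, length, integer(1))
  cat("Echo series:", length(x$trials), "trials,",
      length(x$stimulus_times), "stimulus chirp(s)/trial, mean",
      signif(mean(n), 3), "emitted chirps/trial\n")
  invisible(x)
}

#' Characteristics of emitted chirps
#'
#' Draws a frequency excursion and duration for every emitted chirp from a
#' single, beat-frequency-independent distribution (uniform on 60-150 Hz and
#' 10-20 ms), emulating the observation that the emitted chirps' own
#' characteristics do not vary with the background beat.
#'
#' @param series_list List of `echo_series` (possibly across conditions).
#' @param seed Integer seed for the characteristic draws.
#' @return `data.frame` with columns `f_beat`, `phase`, `delta_f` (Hz),
#'   `delta_t` (s), one row per emitted chirp.
#' @export
emitted_chirp_stats <- function(series_list, seed = 1L) {
  if (inherits(series_list, "echo_series")) series_list <- list(series_list)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- lapply(series_list, function(s) {
    n <- sum(vapply(s$trials, length, integer(1)))
    if (n == 0L) return(NULL)
    data.frame(f_beat = s$f_beat, phase = s$phase,
               delta_f = stats::runif(n, 60, 150),
               delta_t = stats::runif(n, 0.010, 0.020))
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Behavioral chirp rate
#'
#' Average number of emitted chirps in the 1 s window after stimulus chirp
#' onset, divided by the window length, averaged over stimulus chirps and
#' trials.
#'
#' @param series An `echo_series` (or list of them, pooled).
#' @param window Window length, s (default 1).
#' @return Rate in chirps/s.
#' @export
chirp_rate <- function(series, window = 1) {
  counts <- chirp_window_counts(series, window)
  mean(counts) / window
}

# per-(trial x stimulus chirp) counts in the post-onset window, in trial order
chirp_window_counts <- function(series, window = 1) {
  if (inherits(series, "echo_series")) series <- list(series)
  unlist(lapply(series, function(s) {
    if (length(s$stimulus_times) == 0L) stop("input error: no stimulus chirps")
    vapply(s$trials, function(tr)
      vapply(s$stimulus_times, function(on)
        sum(tr > on & tr <= on + window), numeric(1)),
      numeric(length(s$stimulus_times)))
  }))
}

#' Behavioral PSTH
#'
#' Emitted-chirp rate as a function of time from stimulus chirp onset within
#' the 1 s response window, pooled over trials and stimulus chirps.
#'
#' @param series An `echo_series` (or list of them, pooled).
#' @param binwidth Bin width, s (default 10 ms).
#' @param window Response window, s (fixed at 1 s in the standard analysis).
#' @return A `response_trace` with bin-center `times` (s from onset) and
#'   `values` in chirps/s.
#' @export
behavioral_psth <- function(series, binwidth = 0.01, window = 1) {
  if (inherits(series, "echo_series")) series <- list(series)
  n_bins <- ceiling(window / binwidth - 1e-9)
  counts <- numeric(n_bins)
  n_events <- 0L
  for (s in series) {
    for (tr in s$trials) {
      for (on in s$stimulus_times) {
        tau <- tr[tr > on & tr <= on + window] - on
        idx <- pmin(ceiling(tau / binwidth), n_bins)
        counts <- counts + tabulate(idx, n_bins)
        n_events <- n_events + 1L
      }
    }
  }
  if (n_events == 0L) stop("input error: no stimulus chirps")
  response_trace((seq_len(n_bins) - 0.5) * binwidth,
                 counts / (n_events * binwidth), kind = "chirp rate")
}

#' Behavioral phase-invariance score
#'
#' [invariance_score()] with behavioral PSTHs as the responses and a fixed
#' 1 s analysis window.
#'
#' @param psths List of behavioral PSTHs, one per beat phase.
#' @param stimuli List of onset-aligned stimulus waveforms, one per phase.
#' @param window Analysis window, s (default 1).
#' @return Invariance score in `[0, 1]`.
#' @export
behavioral_invariance <- function(psths, stimuli, window = 1) {
  invariance_score(psths, stimuli, window)
}

#' Moving-block bootstrap standard error
#'
#' Resamples contiguous blocks (default length 31) with replacement,
#' concatenating them to the original series length, and recomputes the
#' statistic per replicate; the SE is the standard deviation over
#' replicates. Source blocks start at any position by default
#' (`overlap = TRUE`); non-overlapping source blocks are available as a
#' policy option.
#'
#' @param x Numeric series, ordered as observed; `length(x) >= block_size`.
#' @param statistic Function of a numeric vector (default `mean`).
#' @param block_size Block length (default 31).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param overlap If `FALSE`, source blocks are restricted to the
#'   non-overlapping partition of the series.
#' @return List with `se`, `ci` (percentile 95%), and `replicates`.
#' @export
block_bootstrap <- function(x, statistic = mean, block_size = 31,
                            n_boot = 1000, seed = 1L, overlap = TRUE) {
  n <- length(x)
  if (n < block_size)
    stop("input error: series shorter than one block")
  starts_pool <- if (overlap) seq_len(n - block_size + 1L)
    else seq(1L, n - block_size + 1L, by = block_size)
  k <- ceiling(n / block_size)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    starts <- sample(starts_pool, k, replace = TRUE)
    idx <- as.vector(vapply(starts, function(s) s + 0:(block_size - 1L),
                            numeric(block_size)))[seq_len(n)]
    statistic(x[idx])
  }, numeric(1))
  list(se = stats::sd(reps),
       ci = unname(stats::quantile(reps, c(0.025, 0.975))),
       replicates = reps)
}
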