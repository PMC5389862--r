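#' Beat-scaled sliding-window length
#'
#' The correlation window is 12.5% of the beat period, `T = 0.125/f_beat`
#' (1 Hz: 125 ms, 64 Hz: 1.95 ms, 128 Hz: 0.98 ms), so the window tracks the
#' shrinking chirp-evoked response as the beat frequency grows.
#'
#' @param f_beat Beat frequency, Hz (> 0).
#' @return Window length in seconds.
#' @export
window_length <- function(f_beat) {
  if (!is.numeric(f_beat) || any(f_beat <= 0))
    stop("parameter error: 'f_beat' must be > 0")
  0.125 / f_beat
}

#' Time-resolved pairwise spike-count correlation
#'
#' Slides a window of length `T = window_fraction/f_beat` in steps of
#' `slide_fraction/f_beat` seconds. At each position the window is split into
#' `n_bins` bins; the per-trial, per-bin spike counts of the two afferents
#' form paired count series (pooled over bins and trials), whose Pearson
#' correlation `rho = Cov(n_i, n_j)/sqrt(Var(n_i) Var(n_j))` is reported at
#' the window center. Windows where either count series has zero variance
#' (e.g. mutual silence under rectification) are undefined and carried as
#' `NA`, not zero.
#'
#' @param trains_i,trains_j `spike_trains` of the two afferents; equal trial
#'   counts, trials aligned to the stimulus.
#' @param f_beat Beat frequency, Hz.
#' @param t_start,t_end Span (s) over which windows are placed; defaults to
#'   the full trial. Window start positions lie on the absolute grid
#'   `k * slide_step`, so traces from different conditions share positions.
#' @param n_bins Bins per window (default 5).
#' @param window_fraction Window length as a fraction of the beat period
#'   (default 0.125).
#' @param slide_fraction Slide step as a fraction of the beat period
#'   (default 0.001).
#' @param per_trial If `TRUE`, correlate per trial (across bins) and average
#'   the per-trial coefficients instead of pooling bins x trials. The pooled
#'   reading is the default.
#' @return A `correlation_trace`: `times` (window centers, s), `values`
#'   (rho, `NA` where undefined), plus window metadata.
#' @export
sliding_correlation <- function(trains_i, trains_j, f_beat,
                                t_start = 0, t_end = NULL, n_bins = 5,
                                window_fraction = 0.125,
                                slide_fraction = 0.001, per_trial = FALSE) {
  stopifnot(inherits(trains_i, "spike_trains"),
            inherits(trains_j, "spike_trains"))
  if (trains_i$n_trials != trains_j$n_trials)
    stop("both afferents must have equal trial counts")
  if (f_beat <= 0) stop("parameter error: 'f_beat' must be > 0")
  Tw <- window_fraction / f_beat
  step <- slide_fraction / f_beat
  if (is.null(t_end)) t_end <- min(trains_i$duration, trains_j$duration)
  k0 <- ceiling(t_start / step - 1e-9)
  k1 <- floor((t_end - Tw) / step + 1e-9)
  if (k1 < k0) stop("span too short for one window")
  positions <- (k0:k1) * step
  n_w <- length(positions)
  edges <- outer(positions, Tw * (0:n_bins) / n_bins, "+")  # n_w x (n_bins+1)

  count_mat <- function(st) {
    # counts in half-open [a, b): #spikes <= b minus #spikes <= a
    cnt <- matrix(findInterval(edges, st), nrow = n_w)
    cnt[, -1, drop = FALSE] - cnt[, -(n_bins + 1), drop = FALSE]
  }

  n_trials <- trains_i$n_trials
  if (!per_trial) {
    Sx <- Sy <- Sxx <- Syy <- Sxy <- numeric(n_w)
    for (k in seq_len(n_trials)) {
      ci <- count_mat(sort(trains_i$trains[[k]]))
      cj <- count_mat(sort(trains_j$trains[[k]]))
      Sx <- Sx + rowSums(ci); Sy <- Sy + rowSums(cj)
      Sxx <- Sxx + rowSums(ci * ci); Syy <- Syy + rowSums(cj * cj)
      Sxy <- Sxy + rowSums(ci * cj)
    }
    N <- n_bins * n_trials
    vx <- N * Sxx - Sx^2
    vy <- N * Syy - Sy^2
    rho <- rep(NA_real_, n_w)
    ok <- vx > 0 & vy > 0
    rho[ok] <- (N * Sxy[ok] - Sx[ok] * Sy[ok]) / sqrt(vx[ok] * vy[ok])
  } else {
    acc <- matrix(NA_real_, n_w, n_trials)
    for (k in seq_len(n_trials)) {
      ci <- count_mat(sort(trains_i$trains[[k]]))
      cj <- count_mat(sort(trains_j$trains[[k]]))
      mx <- rowMeans(ci); my <- rowMeans(cj)
      vx <- rowMeans(ci * ci) - mx^2
      vy <- rowMeans(cj * cj) - my^2
      ok <- vx > 0 & vy > 0
      r <- rep(NA_real_, n_w)
      r[ok] <- (rowMeans(ci * cj)[ok] - mx[ok] * my[ok]) / sqrt(vx[ok] * vy[ok])
      acc[, k] <- r
    }
    rho <- rowMeans(acc, na.rm = TRUE)
    rho[!is.finite(rho)] <- NA_real_
  }

  structure(list(times = positions + Tw / 2, values = rho, f_beat = f_beat,
                 window_length = Tw, step = step, n_bins = n_bins,
                 kind = "rho"),
            class = c("correlation_trace", "response_trace"))
}

#' Population-averaged sliding spike-count correlation
#'
#' The rho time course of [sliding_correlation()], averaged pointwise over
#' all unordered afferent pairs of a simulated population (the
#' population-averaged correlated activity used by the standard analysis;
#' single pairs are too noisy for stable range statistics). Count matrices
#' are computed once per afferent and shared across pairs. Windows undefined
#' for a pair are excluded from that point's average; points undefined for
#' every pair stay `NA`.
#'
#' @param pop List of >= 2 `spike_trains` (one per afferent), equal trial
#'   counts, trials aligned to the stimulus.
#' @inheritParams sliding_correlation
#' @return A `correlation_trace` of the pair-averaged rho.
#' @export
population_correlation <- function(pop, f_beat, t_start = 0, t_end = NULL,
                                   n_bins = 5, window_fraction = 0.125,
                                   slide_fraction = 0.001) {
  if (length(pop) < 2L) stop("configuration error: need >= 2 afferents")
  n_aff <- length(pop)
  n_trials <- pop[[1]]$n_trials
  if (!all(vapply(pop, function(p) p$n_trials, integer(1)) == n_trials))
    stop("all afferents must have equal trial counts")
  if (f_beat <= 0) stop("parameter error: 'f_beat' must be > 0")
  Tw <- window_fraction / f_beat
  step <- slide_fraction / f_beat
  if (is.null(t_end)) t_end <- min(vapply(pop, function(p) p$duration,
                                          numeric(1)))
  k0 <- ceiling(t_start / step - 1e-9)
  k1 <- floor((t_end - Tw) / step + 1e-9)
  if (k1 < k0) stop("span too short for one window")
  positions <- (k0:k1) * step
  n_w <- length(positions)
  edges <- outer(positions, Tw * (0:n_bins) / n_bins, "+")

  pairs <- utils::combn(n_aff, 2)
  n_pairs <- ncol(pairs)
  S <- matrix(0, n_w, n_aff)     # sums per afferent
  SS <- matrix(0, n_w, n_aff)    # sums of squares per afferent
  SXY <- matrix(0, n_w, n_pairs) # cross-products per pair
  for (k in seq_len(n_trials)) {
    cm <- lapply(pop, function(p) {
      cnt <- matrix(findInterval(edges, sort(p$trains[[k]])), nrow = n_w)
      cnt[, -1, drop = FALSE] - cnt[, -(n_bins + 1), drop = FALSE]
    })
    for (a in seq_len(n_aff)) {
      S[, a] <- S[, a] + rowSums(cm[[a]])
      SS[, a] <- SS[, a] + rowSums(cm[[a]] * cm[[a]])
    }
    for (p in seq_len(n_pairs))
      SXY[, p] <- SXY[, p] + rowSums(cm[[pairs[1, p]]] * cm[[pairs[2, p]]])
  }
  N <- n_bins * n_trials
  V <- N * SS - S * S                      # N^2 * variance, per afferent
  rho_sum <- numeric(n_w)
  rho_n <- integer(n_w)
  for (p in seq_len(n_pairs)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    ok <- V[, i] > 0 & V[, j] > 0
    r <- (N * SXY[ok, p] - S[ok, i] * S[ok, j]) / sqrt(V[ok, i] * V[ok, j])
    rho_sum[ok] <- rho_sum[ok] + r
    rho_n[ok] <- rho_n[ok] + 1L
  }
  rho <- ifelse(rho_n > 0, rho_sum / pmax(rho_n, 1L), NA_real_)

  structure(list(times = positions + Tw / 2, values = rho, f_beat = f_beat,
                 window_length = Tw, step = step, n_bins = n_bins,
                 n_pairs = n_pairs, kind = "rho"),
            class = c("correlation_trace", "response_trace"))
}

#' Re-zero a trace at chirp onset
#'
#' Subtracts the chirp onset time so that time 0 marks chirp onset (any 9 ms
#' neural delay compensation is applied upstream via [shift_response()]).
#' With `onset = NULL` (a beat-only trace) the trace is returned unchanged.
#'
#' @param trace A `response_trace` / `correlation_trace`.
#' @param chirp_onset Chirp onset time on the trace's current axis, or
#'   `NULL`.
#' @return The trace with `times - chirp_onset`.
#' @export
align_to_chirp <- function(trace, chirp_onset) {
  if (is.null(chirp_onset)) return(trace)
  trace$times <- trace$times - chirp_onset
  trace
}
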