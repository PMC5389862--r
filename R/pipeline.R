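#' Configuration of a full chirp-coding experiment
#'
#' Bundles and validates every knob of the simulation + analysis grid:
#' the stimulus defaults (60 Hz excursion, 14 ms duration, the 8 beat
#' frequencies 1-128 Hz and 8 chirp phases on the 45 degree grid), the
#' afferent and behavior generator parameters, and the analysis settings
#' (correlation window fractions, duration threshold, 9 ms neural delay).
#'
#' @param frequencies Beat frequencies, Hz.
#' @param phases Chirp phases, degrees.
#' @param delta_f,delta_t,contrast,sample_rate Stimulus parameters; see
#'   [stimulus_spec()].
#' @param afferent An [afferent_params()] template; `n_afferents` population
#'   members with independent seeds are derived from it.
#' @param n_afferents Simulated population size (>= 2); correlations are
#'   averaged over all unordered pairs.
#' @param echo An [echo_params()] template.
#' @param neural_delay Axonal delay compensation applied to neural traces, s.
#' @param n_phase_bins Phase-histogram bins for the phase-locking index.
#' @param duration_k Response-duration threshold, in baseline SDs.
#' @param window_fraction,slide_fraction,corr_bins Sliding-correlation
#'   settings (fractions of the beat period; bins per window).
#' @param corr_span_cycles Beat cycles on each side of chirp onset over which
#'   the correlation trace is computed.
#' @param seed Master seed; all per-condition seeds derive from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(frequencies = c(1, 2, 4, 8, 16, 32, 64, 128),
                       phases = seq(0, 315, by = 45),
                       delta_f = 60, delta_t = 0.014, contrast = 0.34,
                       sample_rate = 10000,
                       afferent = afferent_params(), n_afferents = 4,
                       echo = echo_params(),
                       neural_delay = 0.009, n_phase_bins = 20,
                       duration_k = 2, window_fraction = 0.125,
                       slide_fraction = 0.001, corr_bins = 5,
                       corr_span_cycles = 2.2, seed = 1L) {
  stopifnot(length(frequencies) >= 1, all(frequencies > 0),
            length(phases) >= 2, all(phases >= 0), all(phases < 360),
            inherits(afferent, "afferent_params"), n_afferents >= 2,
            inherits(echo, "echo_params"),
            neural_delay >= 0, duration_k > 0, corr_span_cycles > 0)
  cfg <- list(frequencies = frequencies, phases = phases, delta_f = delta_f,
              delta_t = delta_t, contrast = contrast,
              sample_rate = sample_rate, afferent = afferent,
              n_afferents = as.integer(n_afferents), echo = echo,
              neural_delay = neural_delay, n_phase_bins = n_phase_bins,
              duration_k = duration_k, window_fraction = window_fraction,
              slide_fraction = slide_fraction, corr_bins = corr_bins,
              corr_span_cycles = corr_span_cycles, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

derive_seed <- function(base, k) {
  as.integer((as.numeric(base) %% 100000) * 10007 + k * 97) %% 2147483647L
}

# one afferent_params per population member, with derived seeds
population_params <- function(cfg, condition_idx) {
  lapply(seq_len(cfg$n_afferents), function(a) {
    p <- cfg$afferent
    p$noise_seed <- derive_seed(cfg$seed, condition_idx * 10 + a)
    p
  })
}

#' Run the full simulation + analysis experiment
#'
#' For every (beat frequency, chirp phase) cell: synthesizes the stimulus,
#' simulates a pair of afferents, computes PSTHs and sliding spike-count
#' correlations (both delay-compensated and chirp-onset aligned), measures
#' response durations, fits the duration power laws, and scores stimulus,
#' single-unit, and correlation-based detectability and invariance. A
#' behavioral stage then drives the echo-chirp generator with the
#' correlation-based detectability and analyses the emitted series. Fully
#' deterministic under `cfg$seed`. A failing cell is recorded with its error
#' message and the remaining cells complete.
#'
#' @param cfg A [run_config()].
#' @param verbose Print per-stage progress to stderr.
#' @return Object of class `chirp_experiment` with elements `scores` (tidy
#'   data.frame: f_beat, phase, source, metric, value), `durations`,
#'   `duration_fits`, `pli`, `behavior` (per-frequency summary with bootstrap
#'   SEs), `traces` (onset-aligned responses), `errors`, and `config`.
#' @export
run_experiment <- function(cfg = run_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(...)
  freqs <- cfg$frequencies
  phases <- cfg$phases
  errors <- list()
  per_f <- vector("list", length(freqs))
  names(per_f) <- as.character(freqs)
  cond_idx <- 0L

  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    say("beat frequency ", f, " Hz")
    res <- tryCatch({
      base_spec <- stimulus_spec(f_beat = f, chirp_phase = 0,
                                 delta_f = cfg$delta_f, delta_t = cfg$delta_t,
                                 contrast = cfg$contrast,
                                 sample_rate = cfg$sample_rate)
      beat_am <- make_beat(base_spec)
      specs <- phase_grid(base_spec, phases)
      onsets <- vapply(specs, function(s) s$chirp_onset, numeric(1))
      span <- cfg$corr_span_cycles / f

      # beat-only population: reference PSTH, correlation trace, PLI
      cond_idx <- cond_idx + 1L
      pop_beat <- make_population(beat_am, population_params(cfg, cond_idx))
      beat_all <- spike_trains(do.call(c, lapply(pop_beat, `[[`, "trains")),
                               pop_beat[[1]]$duration)
      psth_beat <- shift_response(psth(beat_all), cfg$neural_delay)
      rho_beat <- shift_response(
        population_correlation(pop_beat, f,
                               t_start = max(0, min(onsets) - span),
                               t_end = min(beat_am$spec$total_duration,
                                           max(onsets) + span),
                               n_bins = cfg$corr_bins,
                               window_fraction = cfg$window_fraction,
                               slide_fraction = cfg$slide_fraction),
        cfg$neural_delay)
      ph <- phase_histogram(pop_beat[[1]], f, n_bins = cfg$n_phase_bins)
      pli <- phase_locking_index(ph)
      rate_beat <- rate_from_am(beat_am, cfg$afferent)
      rectified <- any(rate_beat$values == 0)

      cell <- list()
      for (pi in seq_along(phases)) {
        cond_idx <- cond_idx + 1L
        spec <- specs[[pi]]
        am <- insert_chirp(spec)
        onset <- spec$chirp_onset
        pop <- make_population(am, population_params(cfg, cond_idx))
        all_tr <- spike_trains(do.call(c, lapply(pop, `[[`, "trains")),
                               pop[[1]]$duration)
        psth_c <- shift_response(psth(all_tr), cfg$neural_delay)
        rho_c <- shift_response(
          population_correlation(pop, f,
                                 t_start = max(0, onset - span),
                                 t_end = min(spec$total_duration,
                                             onset + span),
                                 n_bins = cfg$corr_bins,
                                 window_fraction = cfg$window_fraction,
                                 slide_fraction = cfg$slide_fraction),
          cfg$neural_delay)
        base_win <- c(max(0, onset - 2 / f), onset)
        adv_s <- chirp_profile_area(cfg$delta_f, cfg$delta_t) / f
        psth_ref <- phase_advanced_reference(psth_beat, onset, cfg$delta_t,
                                             adv_s)
        rho_ref <- phase_advanced_reference(rho_beat, onset, cfg$delta_t,
                                            adv_s)
        cell[[pi]] <- list(
          phase = phases[pi], onset = onset,
          stim_det = stimulus_detectability(am, beat_am),
          dur_su = response_duration(psth_c, psth_ref, onset,
                                     baseline_window = base_win,
                                     k = cfg$duration_k, smooth = 0.5 / f),
          dur_corr = response_duration(rho_c, rho_ref, onset,
                                       baseline_window = base_win,
                                       k = cfg$duration_k, smooth = 0.5 / f),
          psth = align_to_chirp(psth_c, onset),
          rho = align_to_chirp(rho_c, onset),
          psth_beat_al = align_to_chirp(psth_beat, onset),
          rho_beat_al = align_to_chirp(rho_beat, onset),
          stim = align_to_chirp(list(times = am$times, values = am$values),
                                onset))
      }
      list(f = f, cell = cell, pli = pli, rectified = rectified,
           beat_waveforms = lapply(specs, insert_chirp))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(f)]] <- conditionMessage(res)
      say("  failed: ", conditionMessage(res))
    } else per_f[[as.character(f)]] <- res
  }

  ok_f <- !vapply(per_f, is.null, logical(1))
  per_f <- per_f[ok_f]
  if (length(per_f) == 0L) stop("all frequency cells failed")
  freqs_ok <- vapply(per_f, function(x) x$f, numeric(1))

  # response-duration power laws (mean over phases per frequency)
  say("fitting response-duration power laws")
  dur_su <- vapply(per_f, function(x)
    mean(vapply(x$cell, function(c) c$dur_su, numeric(1)), na.rm = TRUE),
    numeric(1))
  dur_corr <- vapply(per_f, function(x)
    mean(vapply(x$cell, function(c) c$dur_corr, numeric(1)), na.rm = TRUE),
    numeric(1))
  fit_su <- if (sum(is.finite(dur_su)) >= 3)
    fit_duration_powerlaw(dur_su, freqs_ok) else NULL
  fit_corr <- if (sum(is.finite(dur_corr)) >= 3)
    fit_duration_powerlaw(dur_corr, freqs_ok) else NULL

  # scores
  say("scoring invariance and detectability")
  rows <- list()
  add_row <- function(f, phase, source, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      f_beat = f, phase = phase, source = source, metric = metric,
      value = value, stringsAsFactors = FALSE)

  for (x in per_f) {
    f <- x$f
    w_su <- if (!is.null(fit_su))
      min(stats::predict(fit_su, f), 2 / f) else cfg$delta_t
    w_corr <- if (!is.null(fit_corr))
      min(stats::predict(fit_corr, f), 2 / f) else cfg$delta_t
    stim_dets <- vapply(x$cell, function(c) c$stim_det, numeric(1))
    for (c_ in x$cell) {
      add_row(f, as.character(c_$phase), "stimulus", "detectability",
              c_$stim_det)
      det_su <- neuronal_detectability(c_$psth, c_$psth_beat_al,
                                       chirp_window = c(0, w_su),
                                       beat_window = c(0, 1 / f))
      det_co <- neuronal_detectability(c_$rho, c_$rho_beat_al,
                                       chirp_window = c(0, w_corr),
                                       beat_window = c(0, 1 / f))
      add_row(f, as.character(c_$phase), "single_unit", "detectability",
              det_su)
      add_row(f, as.character(c_$phase), "correlation", "detectability",
              det_co)
    }
    add_row(f, "all", "stimulus", "detectability", mean(stim_dets))
    add_row(f, "all", "stimulus", "distance",
            inter_chirp_distance(x$beat_waveforms, cfg$delta_t))
    for (src in c("single_unit", "correlation")) {
      det <- vapply(rows, function(r)
        if (r$f_beat == f && r$source == src && r$phase != "all")
          r$value else NA_real_, numeric(1))
      add_row(f, "all", src, "detectability", mean(det, na.rm = TRUE))
    }
    stims <- lapply(x$cell, function(c) c$stim)
    add_row(f, "all", "single_unit", "invariance",
            invariance_score(lapply(x$cell, function(c) c$psth), stims, w_su))
    add_row(f, "all", "correlation", "invariance",
            invariance_score(lapply(x$cell, function(c) c$rho), stims, w_corr))
  }
  scores <- do.call(rbind, rows)

  # behavioral stage, driven by correlation-based detectability per phase
  say("behavioral stage")
  behavior_rows <- list()
  for (x in per_f) {
    f <- x$f
    drive_tab <- vapply(x$cell, function(c_) {
      d <- scores$value[scores$f_beat == f & scores$source == "correlation" &
                          scores$metric == "detectability" &
                          scores$phase == as.character(c_$phase)]
      if (length(d) == 0L || !is.finite(d)) 0 else min(1, max(0, d))
    }, numeric(1))
    series <- vector("list", length(x$cell))
    for (pi in seq_along(x$cell)) {
      ep <- cfg$echo
      ep$seed <- derive_seed(cfg$seed, 100000 + which(freqs_ok == f) * 100 + pi)
      series[[pi]] <- simulate_echoes(stimulus_times = 0.5,
                                      trial_duration = 2,
                                      drive = drive_tab[pi], params = ep,
                                      f_beat = f, phase = x$cell[[pi]]$phase)
    }
    # behavioral stimuli: regenerate with >= 1 s after onset for the 1 s window
    bspec <- stimulus_spec(f_beat = f, chirp_phase = 0, delta_f = cfg$delta_f,
                           delta_t = cfg$delta_t, contrast = cfg$contrast,
                           sample_rate = cfg$sample_rate,
                           total_duration = (2 + 315 / 360) / f + 1.1)
    bstims <- lapply(phase_grid(bspec, phases), function(s) {
      w <- insert_chirp(s)
      list(times = w$times - w$chirp_onset, values = w$values)
    })
    psths <- lapply(series, behavioral_psth)
    inv_b <- behavioral_invariance(psths, bstims, window = 1)
    counts <- chirp_window_counts(series, 1)
    rate <- mean(counts)
    boot <- block_bootstrap(counts, statistic = mean, block_size = 31,
                            n_boot = 500,
                            seed = derive_seed(cfg$seed, 999000 + round(f)))
    behavior_rows[[length(behavior_rows) + 1L]] <- data.frame(
      f_beat = f, chirp_rate = rate, chirp_rate_se = boot$se,
      invariance = inv_b, n_windows = length(counts))
    scores <- rbind(scores,
                    data.frame(f_beat = f, phase = "all", source = "behavior",
                               metric = "detectability", value = rate,
                               stringsAsFactors = FALSE),
                    data.frame(f_beat = f, phase = "all", source = "behavior",
                               metric = "invariance", value = inv_b,
                               stringsAsFactors = FALSE))
  }
  behavior <- do.call(rbind, behavior_rows)

  structure(list(
    scores = scores[order(scores$f_beat, scores$source, scores$metric), ],
    durations = data.frame(f_beat = freqs_ok, single_unit = dur_su,
                           correlation = dur_corr),
    duration_fits = list(single_unit = fit_su, correlation = fit_corr),
    pli = data.frame(f_beat = freqs_ok,
                     pli = vapply(per_f, function(x) x$pli, numeric(1)),
                     rectified = vapply(per_f, function(x) x$rectified,
                                        logical(1))),
    behavior = behavior,
    traces = lapply(per_f, function(x)
      list(f_beat = x$f,
           psth = lapply(x$cell, function(c) c$psth),
           rho = lapply(x$cell, function(c) c$rho),
           psth_beat = x$cell[[1]]$psth_beat_al,
           rho_beat = x$cell[[1]]$rho_beat_al)),
    errors = errors, config = cfg),
    class = "chirp_experiment")
}

# tidy score lookup helper
score_value <- function(expt, source, metric, f_beat = NULL, phase = "all") {
  s <- expt$scores
  sel <- s$source == source & s$metric == metric & s$phase == phase
  if (!is.null(f_beat)) sel <- sel & s$f_beat %in% f_beat
  out <- s[sel, c("f_beat", "value")]
  out[order(out$f_beat), ]
}

#' @export
print.chirp_experiment <- function(x, ...) {
  cat("Chirp-coding experiment:", length(unique(x$scores$f_beat)),
      "beat frequencies x", length(x$config$phases), "phases,",
      x$config$afferent$n_trials, "trials/afferent\n")
  if (length(x$errors))
    cat("  failed cells:", paste(names(x$errors), collapse = ", "), "\n")
  cat("Use summary() for the score table.\n")
  invisible(x)
}

#' @export
summary.chirp_experiment <- function(object, ...) {
  inv <- score_value(object, "correlation", "invariance")
  inv_su <- score_value(object, "single_unit", "invariance")
  det <- score_value(object, "correlation", "detectability")
  det_su <- score_value(object, "single_unit", "detectability")
  stim <- score_value(object, "stimulus", "detectability")
  out <- data.frame(f_beat = inv$f_beat,
                    stimulus_detectability = stim$value,
                    invariance_single_unit = inv_su$value,
                    invariance_correlation = inv$value,
                    detectability_single_unit = det_su$value,
                    detectability_correlation = det$value)
  out <- merge(out, object$behavior[, c("f_beat", "chirp_rate",
                                        "chirp_rate_se", "invariance")],
               by = "f_beat", all.x = TRUE)
  names(out)[names(out) == "invariance"] <- "invariance_behavior"
  out[order(out$f_beat), ]
}

#' @export
plot.chirp_experiment <- function(x, ...) {
  s <- summary(x)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(s$f_beat,
                    s[, c("invariance_single_unit", "invariance_correlation",
                          "invariance_behavior")],
                    type = "b", log = "x", pch = 16, lty = 1,
                    col = c("blue", "purple", "brown"),
                    xlab = "beat frequency (Hz)", ylab = "invariance", ...)
  graphics::matplot(s$f_beat,
                    s[, c("detectability_single_unit",
                          "detectability_correlation")],
                    type = "b", log = "x", pch = 16, lty = 1,
                    col = c("blue", "purple"),
                    xlab = "beat frequency (Hz)", ylab = "detectability", ...)
  invisible(x)
}

#' Property checks on a completed experiment
#'
#' Evaluates the headline structural claims on the experiment's own outputs:
#' stimulus detectability decreasing with beat frequency while inter-chirp
#' distances stay constant; phase locking and rectification confined to high
#' beat frequencies; correlation-based invariance and detectability degrading
#' from low to high beat frequency with single-unit invariance below
#' correlation-based invariance at the lowest frequency; and behavior
#' tracking the correlation-based scores.
#'
#' @param expt A `chirp_experiment`.
#' @param f_low,f_high The two anchor frequencies compared (defaults 2 and
#'   64 Hz, or the extremes of the run's grid).
#' @return `data.frame` of (check, pass) with attribute `ok`; printed with
#'   pass/fail marks.
#' @export
acceptance_report <- function(expt, f_low = NULL, f_high = NULL) {
  stopifnot(inherits(expt, "chirp_experiment"))
  fs <- sort(unique(expt$scores$f_beat))
  if (is.null(f_low)) f_low <- if (2 %in% fs) 2 else min(fs)
  if (is.null(f_high)) f_high <- if (64 %in% fs) 64 else max(fs)
  g <- function(source, metric, f) {
    v <- score_value(expt, source, metric, f_beat = f)
    if (nrow(v) == 0) NA_real_ else v$value
  }
  stim <- score_value(expt, "stimulus", "detectability")
  icd <- score_value(expt, "stimulus", "distance")
  checks <- list(
    stimulus_detectability_decreasing =
      g("stimulus", "detectability", f_low) >
      g("stimulus", "detectability", f_high),
    inter_chirp_distance_cv_small =
      stats::sd(icd$value) / mean(icd$value) < 0.15,
    pli_nondecreasing = !is.unsorted(expt$pli$pli[order(expt$pli$f_beat)]),
    rectified_only_high =
      all(!expt$pli$rectified[expt$pli$f_beat <= 10]) &&
      any(expt$pli$rectified[expt$pli$f_beat >= f_high]),
    correlation_invariance_degrades =
      g("correlation", "invariance", f_low) >
      g("correlation", "invariance", f_high),
    correlation_detectability_degrades =
      g("correlation", "detectability", f_low) >
      g("correlation", "detectability", f_high),
    single_unit_invariance_low =
      g("single_unit", "invariance", f_low) <
      g("correlation", "invariance", f_low),
    behavior_rate_decreases =
      g("behavior", "detectability", f_low) >
      g("behavior", "detectability", f_high),
    behavior_invariance_decreases =
      g("behavior", "invariance", f_low) >
      g("behavior", "invariance", f_high),
    behavior_tracks_correlation_rank =
      stats::cor(score_value(expt, "behavior", "detectability")$value,
                 score_value(expt, "correlation", "detectability")$value,
                 method = "spearman") == 1
  )
  out <- data.frame(check = names(checks),
                    pass = vapply(checks, isTRUE, logical(1)))
  attr(out, "ok") <- all(out$pass)
  class(out) <- c("acceptance_report", class(out))
  out
}

#' @export
print.acceptance_report <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-40s %s\n", x$check[i],
                if (x$pass[i]) "PASS" else "FAIL"))
  cat(if (attr(x, "ok")) "All checks passed.\n" else "Some checks FAILED.\n")
  invisible(x)
}
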