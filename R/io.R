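#' Write an AM waveform as a two-column CSV
#'
#' Columns `time_s`, `amplitude_mVcm`; the stimulus spec is stored in `#`
#' header comment lines.
#'
#' @param am An `am_waveform`.
#' @param path Output file path.
#' @export
write_waveform_csv <- function(am, path) {
  spec <- am$spec
  hdr <- sprintf("# f_beat=%g chirp_phase=%g delta_f=%g delta_t=%g contrast=%g sample_rate=%g",
                 spec$f_beat, spec$chirp_phase, spec$delta_f, spec$delta_t,
                 spec$contrast, spec$sample_rate)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(time_s = am$times, amplitude_mVcm = am$values),
                   con, row.names = FALSE)
}

#' Read an AM waveform written by [write_waveform_csv()]
#' @param path File path.
#' @return A list with `times` and `values` (spec metadata as attributes).
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  list(times = d$time_s, values = d$amplitude_mVcm)
}

#' Write spike trains as a per-trial event CSV
#'
#' Columns `trial`, `spike_time_s`.
#'
#' @param trains A `spike_trains` object.
#' @param path Output file path.
#' @export
write_spikes_csv <- function(trains, path) {
  tl <- as_train_list(trains)
  d <- data.frame(
    trial = rep(seq_along(tl), vapply(tl, length, integer(1))),
    spike_time_s = unlist(tl))
  utils::write.csv(d, path, row.names = FALSE)
}

#' Read spike trains from a per-trial event CSV
#' @param path File path.
#' @param duration Trial duration, s; defaults to just past the last spike.
#' @param n_trials Number of trials; defaults to the largest trial id.
#' @return A `spike_trains` object.
#' @export
read_spikes_csv <- function(path, duration = NULL, n_trials = NULL) {
  d <- utils::read.csv(path)
  if (is.null(n_trials)) n_trials <- max(d$trial)
  if (is.null(duration)) duration <- max(d$spike_time_s) + 1e-3
  spike_trains(lapply(seq_len(n_trials),
                      function(k) sort(d$spike_time_s[d$trial == k])),
               duration)
}

#' Write an echo series as an event CSV
#'
#' Columns `trial`, `event_type` (stimulus | emitted), `time_s`, `f_beat`,
#' `phase`.
#'
#' @param series An `echo_series`.
#' @param path Output file path.
#' @export
write_echo_csv <- function(series, path) {
  rows <- list()
  for (k in seq_along(series$trials)) {
    rows[[length(rows) + 1L]] <- data.frame(
      trial = k, event_type = "stimulus", time_s = series$stimulus_times,
      f_beat = series$f_beat, phase = series$phase)
    if (length(series$trials[[k]]))
      rows[[length(rows) + 1L]] <- data.frame(
        trial = k, event_type = "emitted", time_s = series$trials[[k]],
        f_beat = series$f_beat, phase = series$phase)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Serialize a run configuration to JSON
#' @param cfg A [run_config()].
#' @param path Output file path.
#' @export
write_config_json <- function(cfg, path) {
  jsonlite::write_json(unclass_deep(cfg), path, auto_unbox = TRUE,
                       digits = NA)
}

#' Read a run configuration from JSON
#' @param path File path written by [write_config_json()].
#' @return A [run_config()].
#' @export
read_config_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(frequencies = j$frequencies, phases = j$phases,
             delta_f = j$delta_f, delta_t = j$delta_t, contrast = j$contrast,
             sample_rate = j$sample_rate,
             afferent = do.call(afferent_params, j$afferent),
             n_afferents = j$n_afferents,
             echo = do.call(echo_params, j$echo),
             neural_delay = j$neural_delay, n_phase_bins = j$n_phase_bins,
             duration_k = j$duration_k,
             window_fraction = j$window_fraction,
             slide_fraction = j$slide_fraction, corr_bins = j$corr_bins,
             corr_span_cycles = j$corr_span_cycles, seed = j$seed)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Write all experiment outputs to a directory
#'
#' Emits the score table and behavior summary as CSV, the duration fits as
#' JSON, and the configuration (with its seed, for provenance) as JSON.
#'
#' @param expt A `chirp_experiment`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_experiment <- function(expt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(expt$scores, file.path(dir, "score_table.csv"),
                   row.names = FALSE)
  utils::write.csv(expt$behavior, file.path(dir, "behavior_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(expt$durations, file.path(dir, "response_durations.csv"),
                   row.names = FALSE)
  utils::write.csv(expt$pli, file.path(dir, "phase_locking.csv"),
                   row.names = FALSE)
  fits <- lapply(expt$duration_fits, function(f)
    if (is.null(f)) NULL else f[c("a", "b", "r_squared", "durations",
                                  "f_beat")])
  jsonlite::write_json(fits, file.path(dir, "duration_fits.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_config_json(expt$config, file.path(dir, "config.json"))
  invisible(dir)
}
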