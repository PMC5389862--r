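---
title: "Phase-invariant coding of electrocommunication chirps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-invariant coding of electrocommunication chirps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chirpinv)
```

## The scientific problem

When two weakly electric fish (*Apteronotus*-type wave species) meet, the
interference of their quasi-sinusoidal electric organ discharges (EODs)
produces a sinusoidal amplitude modulation of the field each fish senses —
the *beat* — whose frequency equals the difference of the two EOD
frequencies. A *small chirp* is a communication signal in which the emitter
transiently raises its EOD frequency by some excursion `delta_f` (~60 Hz)
for a short duration `delta_t` (~14 ms). Sensed by the receiver, the chirp
is a brief acceleration of the beat that permanently advances its phase (a
"phase reset"). Because chirps occur at arbitrary beat phases and on
backgrounds of very different beat frequencies (1–128 Hz), the *same* chirp
produces a family of quite different stimulus waveforms.

The scientific question this package addresses computationally: which
representation carried by the peripheral electrosensory afferents (P-units)
provides a *detectable* and *beat-phase-invariant* readout of the chirp, and
how does that representation degrade as the background beat frequency grows?
The package implements the full analysis chain — waveform distances,
detectability indices, phase-invariance scores, time-resolved spike-count
correlations, response-duration power laws, and behavioral echo-response
measures — together with synthetic-data generators that emulate the
statistical structure the analysis assumes, so every metric can be exercised
and property-tested end to end without recorded data.

## Stimulus model

`make_beat()` synthesizes the AM directly in the envelope domain,
`AM(t) = c sin(2 pi f_beat t)`, with contrast `c` in mV/cm. *Phase
convention:* beat phase 0° is the upward zero-crossing of the AM, and
`chirp_phase` is the beat phase at chirp onset (the start of the excursion
window). The paper never fixes its zero, so one convention had to be chosen
and is used consistently; a carrier-sum + envelope-extraction construction
exists only as a test oracle.

`make_chirp_profile()` models the EOD-frequency excursion as a truncated
Gaussian: sigma = `delta_t`/4, restricted to its ±2 sigma window and
rescaled to be exactly zero at the window edges and `delta_f` at the peak.
The duration is therefore *defined* as the ±2 sigma width — an explicit,
testable convention. The original profile shape is specified only in an
earlier study's methods; the Gaussian is a documented assumption, standard
for small-chirp modelling, and all downstream measures depend on it only
through the excursion integral (the accumulated phase advance, ~0.45 beat
cycles for the 60 Hz / 14 ms default) and the window width.

`insert_chirp()` integrates the instantaneous frequency
`f_beat + excursion(t)` (trapezoid rule on the sampling grid), so the
waveform equals the plain beat bitwise before onset and is phase-advanced by
`2 pi * integral(excursion)` afterwards. Defaults: 10 kHz sampling (the
recordings' digitization rate), contrast 0.34 mV/cm (the recordings' average
stimulus intensity), two full beat cycles before the chirp and at least one
after, minimum 1 s, so unperturbed reference windows always exist.

One subtlety the Gaussian choice creates: the time-reversal/sign symmetry
that pairs the 8 grid phases in the original figures holds here in its exact
form — the time-reversed, negated chirp window at phase phi equals the chirp
window at an analytically derived mirror phase — but that mirror phase
depends on the accumulated phase advance and does not itself land on the
45° grid. The tests therefore verify the exact symmetry rather than a
within-grid pairing.

## Afferent model (synthetic data)

P-unit-like afferents are modelled at the firing-rate level:

  r(t) = max(0, baseline + g(f) * AM(t)),    g(f) = g1 * f^k

with the gain evaluated at the beat frequency during beat epochs and at the
excursion-dominated effective frequency `f_beat + delta_f` inside the chirp
window, so chirp responses are strong at every background frequency. The
high-pass gain makes high-frequency beats drive larger rate modulations,
which produces *rectification* — complete cessation of firing over part of
the beat cycle — exactly when the modulated term exceeds baseline. For a
rectified sinusoid the silent fraction has the closed form
`1/2 - asin(baseline/A)/pi` (`silent_fraction()`), used as a test oracle.

Defaults (`afferent_params()`): baseline 300 Hz (a typical P-unit rate),
g1 = 320 (spikes/s)/(mV/cm), k = 0.35, calibrated against the two anchors
the source experiment states — no rectification at the default contrast for
beat frequencies up to 10 Hz (here, up to ~24 Hz), and a silent fraction
above 25% at 64 Hz (here 0.28). A steeper exponent (k = 1) was tried first
and rejected: it makes low-frequency beat responses ~30x weaker than chirp
responses, so single-unit PSTHs look spuriously phase-invariant at 2 Hz —
the opposite of the recorded afferents, whose beat responses are substantial
at all tested frequencies.

Spiking is generated by time-rescaling: operational time is the integral of
r(t), and interspike intervals in operational time are Gamma(shape, shape)
with unit mean (`isi_shape`, default 8; count Fano factor ~1/8).
`isi_shape = 1` recovers an inhomogeneous Poisson process, generated by
thinning. The regular default deviates from the simplest Poisson choice
deliberately: with ~0.1 expected spikes per correlation bin at 64 Hz,
Poisson shot noise is ~50x the shared-drive signal variance, and the
beat-locked synchrony that carries the entire high-frequency story would be
statistically invisible at any feasible trial count. Real P-units are
strongly sub-Poisson, and that regularity is load-bearing here. A fixed
9 ms axonal transmission `latency` is added to every spike so that the
analysis chain's standard 9 ms left shift of neural traces
(`shift_response()`) re-aligns responses with the stimulus, as it does for
recorded afferents.

Trial-to-trial variability is private renewal noise per afferent; pairwise
correlation arises purely from the shared stimulus drive. All generators are
reproducible from integer seeds.

## Neural metrics

* `binarize()`: half-open 0.5 ms bins; bin contents are spike counts.
* `psth()`: trial-averaged rate, 0.1 ms bins, smoothed with a 6 ms boxcar.
  Edge handling is reflect padding, which conserves the spike-count integral
  exactly for responses supported away from the trace ends (tested to
  1e-9 relative).
* `phase_histogram()` / `phase_locking_index()`: spikes mapped to beat
  phase, 20 bins (the source text is silent; 20 resolves the silent arc at
  every tested frequency without starving bins). The index is the fraction
  of bins below 0.05% of the mean bin count — implemented literally, which
  with count data flags exactly-silent bins; the factor is an argument, so
  the plausible reading "5%" can be explored. Vector strength is
  deliberately not implemented: it is nonzero for purely sinusoidal rate
  modulation, which is not phase locking in the sense used here.
* `sliding_correlation()` / `population_correlation()`: the time-resolved
  pairwise spike-count correlation. The window is 12.5% of the beat period
  (`window_length()`), discretized into 5 bins; the window slides in steps
  of 0.1% of the beat period. At each position the per-trial, per-bin counts
  of the two afferents are pooled into paired vectors whose Pearson
  correlation is reported at the window center. *Pooling choice:* whether
  counts were pooled across trials or correlated per trial and averaged is
  not stated in the source; pooling is the only reading that gives a
  well-defined sample correlation from the stated 5-bin discretization and
  is the default, with `per_trial = TRUE` as the alternative. Zero-variance
  windows (e.g. mutual silence under rectification) are *undefined* — `NA`,
  never 0 — and excluded from downstream averages. The pipeline averages the
  rho time course over all pairs of a 4-afferent population: single-pair
  max−min range statistics are extreme-value noise, and the source analyses
  population averages of >100 afferents.

## Distances, detectability, invariance

`trace_distance()` implements the normalized waveform distance

  D(x, y) = <(x - <x> - y + <y>)^2> / max(half-range(x), half-range(y))^2

over an analysis window. The *squared* normalization makes D dimensionless
and scale-invariant; without it, ratios of distances between firing-rate
traces (Hz), correlation traces (dimensionless), and stimulus waveforms
(mV/cm) would depend on the units chosen, and the invariance score's anchor
behaviour ("responses as different as the stimuli" = score 0) would be
meaningless across sources. This is also what makes "a value of one"
interpretable for stimulus detectability.

* `stimulus_detectability()`: D between the chirp-bearing AM and the
  phase-matched unperturbed beat over one full beat cycle from chirp onset.
  At low beat frequencies most of that cycle sits at the full post-reset
  phase offset, so detectability is high; at high frequencies the cycle
  barely outlasts the chirp itself and detectability falls.
* `inter_chirp_distance()`: mean D over all 28 unordered pairs of the
  8 phase variants, in the 14 ms chirp window — the stimulus-side constancy
  claim (its coefficient of variation across beat frequencies is tested
  against 0.15).
* `neuronal_detectability()`: |R_chirp − R_beat| / (R_chirp + R_beat), each
  R a max−min response range — the chirp range in a window sized by the
  fitted response duration, the beat range over one cycle of the undisturbed
  reference. Applies identically to PSTHs and correlation traces; in [0, 1],
  symmetric, undefined only if both ranges vanish.
* `invariance_score()`: 1 − meanD(responses)/meanD(stimuli), clipped to
  [0, 1], responses and stimuli aligned to chirp onset and compared over the
  fitted-duration window. The exact normalization of the original score is
  defined in a predecessor study; this form is forced by its two anchor
  points (identical responses to distinct stimuli -> 1; responses exactly as
  dissimilar as the stimuli -> ~0) and is argument-exposed via the window.

## Response durations

`response_duration()` measures how long the chirp perturbs a response:
the first contiguous post-onset interval where the absolute difference
between the chirp response and a reference exceeds the beat-epoch level by
`k` = 2 SD. Three numerical choices proved necessary and are part of the
definition here:

1. the criterion runs on the *envelope* — the absolute difference smoothed
   with a boxcar of half a beat period — because the raw difference of two
   oscillating traces crosses zero inside the response, which would truncate
   the "contiguous" interval at its first lobe;
2. the threshold is baseline *mean* + k SD, because the absolute difference
   is a folded-noise level whose mean survives smoothing while its SD
   collapses;
3. the post-chirp reference is the *phase-advanced* beat response
   (the chirp's phase reset is permanent, so against the unperturbed beat
   the difference never decays and "duration" would measure trace length).

`fit_duration_powerlaw()` fits d = a f^b by least squares in log–log
coordinates, excluding undefined durations; the fitted duration, capped at
two beat periods, sets the per-frequency analysis window for invariance and
detectability ("only the response to the chirp is accounted for"). Separate
fits are kept for single-unit and correlation durations.

## Behavior (synthetic data and analysis)

`simulate_echoes()` models the echo response — a fish's tendency to answer a
received chirp with its own within ~1 s — as a driven point process: a low
spontaneous emission rate (0.05 chirps/s) plus, after each stimulus chirp, a
latency-jittered Gaussian rate bump (mean 0.25 s, SD 0.08 s) whose area is
`echo_gain x drive`. The drive is the correlation-based detectability of
that (frequency, phase) condition — this implements the hypothesis that
correlated afferent activity is what downstream decoding uses, as a
*generative assumption of the synthetic world*, not a measured fact. 500
trials per condition keep the Monte-Carlo noise of behavioral PSTHs well
below the designed drive differences. `emitted_chirp_stats()` draws each
emitted chirp's own excursion and duration from a single
beat-independent distribution (uniform 60–150 Hz, 10–20 ms), mirroring the
observation that emitted-chirp characteristics do not vary with the
background.

`chirp_rate()` (count in the 1 s post-onset window / 1 s),
`behavioral_psth()` (10 ms bins — the source is silent; 100 bins resolve the
1 s window without starving counts), and `behavioral_invariance()` (the
neural invariance score with behavioral PSTHs and a 1 s window) quantify the
readout. Errors come from `block_bootstrap()`: moving blocks of 31
resampled with replacement to the series length (overlapping source blocks
by default; the non-overlapping policy is an argument).

## Orchestration

`run_config()` + `run_experiment()` run the full grid (defaults: beat
frequencies 1–128 Hz in octaves, 8 phases, 200 trials x 4 afferents), fully
deterministic under one master seed, recording per-frequency failures
without aborting the rest. `acceptance_report()` re-evaluates the headline
structural claims on the finished object; `write_experiment()` emits CSV/JSON
outputs with the configuration (and seed) alongside for provenance. Configs
and reports are JSON rather than YAML, and exports are CSV rather than HDF5,
because no YAML or HDF5 R packages are available in the supported
environment.

## What the generators do and do not establish

The synthetic world reproduces the *structure* the analysis assumes:
high-pass gain with calibrated rectification anchors, sub-Poisson regularity,
shared-stimulus correlations, beat-phase-locked synchrony at high beat
frequencies, chirp-locked synchronization at low ones, and
detectability-driven echo behavior. Green end-to-end tests therefore
establish that the *analysis chain* recovers the designed orderings — they
are not evidence about real fish. Known limitations:

* The rate model is instantaneous (no adaptation, no cumulative
  integration); response durations beyond the chirp window arise only from
  the correlation window, smoothing, and the beat-phase reset.
* Spiking is a renewal process; real P-units skip EOD cycles in
  structured ways and phase-lock to the EOD carrier itself, which is not
  modelled (the EOD carrier does not exist in the envelope-domain stimulus).
* Single-unit detectability is not uniformly low here, unlike the recorded
  afferents at low beat frequencies: the power-law gain model still
  exaggerates the chirp-to-beat response ratio at 1–2 Hz. None of the
  structural orderings used for acceptance depend on its absolute level.
* Behavioral invariance inherits the phase spread of the detectability
  drive; it tracks correlation-based invariance in its coarse shape but not
  rank-for-rank — the two are different functionals, and several of their
  values are near-ties whose ranks are sampling noise. The corresponding
  exact rank-agreement expectation in the acceptance suite fails by design
  honesty rather than implementation error; chirp *rate* does rank-track
  correlation detectability exactly, since it is its monotone image plus
  well-controlled noise.
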