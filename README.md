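# chirpinv

Phase-invariant coding and detectability of electrocommunication chirps in
weakly electric fish — a simulation and analysis pipeline.

## The problem

When two wave-type electric fish interact, interference of their electric
organ discharges (EODs) produces a sinusoidal amplitude modulation — the
**beat** — at the difference of their EOD frequencies. A **small chirp** is
a communication signal: the emitter transiently raises its EOD frequency by
`Δf ≈ 60 Hz` for `Δt ≈ 14 ms`, which the receiver senses as a brief
acceleration and permanent phase advance of the beat. The same chirp
produces very different stimulus waveforms depending on the beat phase at
which it occurs and the background beat frequency (1–128 Hz).

`chirpinv` is for computational neuroscientists who want to study — on
fully synthetic, seeded data — which peripheral representation makes such
chirps *detectable* and *beat-phase-invariant*:

* **stimulus level** — normalized waveform distance
  `D(x,y) = ⟨(x−⟨x⟩−y+⟨y⟩)²⟩ / max(half-range(x), half-range(y))²`,
  chirp-vs-beat detectability over one beat cycle, and inter-chirp
  distances across the 8-phase grid (0°–315° in 45° steps);
* **single afferent level** — P-unit-like rate model
  `r(t) = max(0, r₀ + g(f)·AM(t))` with high-pass gain `g(f) = g₁ f^k`,
  rectification at high beat frequencies, gamma-renewal (sub-Poisson)
  spiking, PSTHs (0.1 ms bins, 6 ms boxcar), phase histograms and a
  phase-locking index;
* **population level** — time-resolved pairwise spike-count correlation
  `ρ = Cov(nᵢ,nⱼ)/√(Var(nᵢ)Var(nⱼ))` in windows of 12.5% of the beat
  period (5 bins, slide step 0.1% of the period), averaged over all pairs
  of a simulated population;
* **scores** — neural detectability `|R_chirp−R_beat|/(R_chirp+R_beat)`
  (R = max−min response range), invariance
  `1 − meanD(responses)/meanD(stimuli)` in windows set by power-law fits
  `d = a·f^b` of the measured response durations;
* **behavior** — echo-chirp emission as a driven point process, chirp rate
  in the 1 s post-chirp window, behavioral invariance, and moving-block
  bootstrap errors (block size 31).

## Worked example

```r
library(chirpinv)

window_length(c(1, 64, 128))    # sliding-window length, 12.5% of the period
#> [1] 0.1250000000 0.0019531250 0.0009765625

spec <- stimulus_spec(f_beat = 2, chirp_phase = 90)
spec
#> Stimulus spec: beat 2 Hz, contrast 0.34 mV/cm
#>   chirp: delta_f 60 Hz, delta_t 14 ms, phase 90 deg, onset 1.125 s
#>   duration 2.452 s at 10000 Hz

e <- run_experiment(run_config(seed = 3))   # full 8 x 8 grid, ~2 min
summary(e)
#>   f_beat stimulus_detectability invariance_single_unit invariance_correlation
#> 1      1                   1.94                  0.486                   0.60
#> 2      2                   1.92                  0.430                   0.77
#> 3      4                   1.89                  0.345                   0.87
#> 4      8                   1.83                  0.239                   0.88
#> 5     16                   1.70                  0.134                   0.72
#> 6     32                   1.44                  0.049                   0.58
#> 7     64                   0.97                  0.238                   0.64
#> 8    128                   0.24                  0.410                   0.73
#>   detectability_single_unit detectability_correlation chirp_rate chirp_rate_se
#> 1                     0.372                      0.44       0.72         0.016
#> 2                     0.304                      0.54       0.85         0.017
#> 3                     0.224                      0.59       0.92         0.015
#> 4                     0.148                      0.67       1.04         0.016
#> 5                     0.077                      0.66       1.02         0.016
#> 6                     0.020                      0.38       0.61         0.016
#> 7                     0.096                      0.20       0.36         0.014
#> 8                     0.240                      0.12       0.23         0.014
#>   invariance_behavior
#> 1                0.96
#> ...

e$duration_fits$correlation
#> Power-law fit d = a * f^b: a = 0.2403 s, b = -0.891 , R^2 = 0.942 ( 8 frequencies )

acceptance_report(e)
#> stimulus_detectability_decreasing        PASS
#> inter_chirp_distance_cv_small            PASS
#> pli_nondecreasing                        PASS
#> rectified_only_high                      PASS
#> correlation_invariance_degrades          PASS
#> correlation_detectability_degrades       PASS
#> single_unit_invariance_low               PASS
#> behavior_rate_decreases                  PASS
#> behavior_invariance_decreases            PASS
#> behavior_tracks_correlation_rank         PASS
#> All checks passed.
```

Reading the table: stimulus detectability falls monotonically with beat
frequency while inter-chirp distances stay constant — the chirp gets harder
to detect against faster beats even though the 8 phase variants remain
equally distinct from one another. Correlation-based invariance and
detectability are high at low beat frequencies and degrade above ~16 Hz,
where afferents phase-lock (rectify) to the beat itself; single-unit
invariance is low throughout. The behavioral chirp rate (the echo-response
readout) follows the correlation-based detectability curve. Response
durations shrink with beat frequency as a power law, which sets the
per-frequency analysis windows.

`plot(e)` draws the invariance and detectability curves;
`write_experiment(e, "out/")` exports the score table, behavior summary,
duration fits, and the seeded configuration.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full experiment from scratch under the given seed —
stimulus grid, afferent population simulation, correlation/invariance/
detectability scoring, duration power laws, and the behavioral stage —
prints the summary table and structural check report, exports the outputs
under `results/experiment/`, and writes the JSON report to `--out`.
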