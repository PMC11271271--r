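# lrdpipe

Analysis of spontaneous synaptic activity in cortical neurons and slice
networks, centered on **large rhythmic depolarizations (LRDs)** —
compound depolarizing events (~0.1–0.7 Hz, ≥ 3 mV, ~150-ms decay)
generated by near-synchronous volleys of excitatory inputs, recorded
intracellularly against a dense background of unitary EPSPs (~10 Hz,
~2 mV, ~40-ms decay). The package is for electrophysiologists who want
the complete, testable analysis stack for such recordings:

* **Event detection and classification** — depolarizing events are
  detected by Wiener deconvolution with a synaptic template, measured by
  local template regression, and classified by the two amplitude
  thresholds: unitary EPSP for amplitudes in [0.2, 3) mV, LRD at
  ≥ 3 mV with a sustained slow envelope. EPSP-like deflections on an
  LRD's decay phase are counted; deflections on its rising phase are
  absorbed into the LRD.
* **Kinetics** — rise time (20→80% of amplitude) and the decay constant
  of a profiled least-squares mono-exponential fit of the falling phase.
* **Intrinsic properties** — resting potential, input resistance (slope
  of the steady-state I–V relation), spike threshold (argmax of
  d²V/dt²), amplitude, half-width, rheobase.
* **Wavelet spectra** — Morlet time–frequency maps and amplitude spectra
  (0.05–100 Hz) with a baseline-noise reference.
* **MEA pipeline** — band-pass filtering, −5 × MAD/0.6745 spike
  detection with 1-ms dead time, firing rates, network-wide
  cumulative-moving-average burst detection clamped to 60–140 ms, and
  LFP detection (3 × SD, ≥ 30 ms).
* **Synchrony statistic** — a co-activity graph (channels sharing spikes
  in the same 200-ms bin are connected) summarized by the mean degree
  centrality `MDC = 2 × edges / nodes`.
* **Synthetic-data generator** — seeded intracellular traces, current
  steps and MEA recordings with planted ground truth matching the event
  statistics above, including norepinephrine (synchronizing: LRD rate
  0.13 → 0.39 Hz) and acetylcholine (desynchronizing: LRD rate
  0.40 → 0.13 Hz, EPSP rate 11.18 → 14.12 Hz) regimes, so every stage
  of the pipeline is verifiable without any recordings.

## Worked example

```r
library(lrdpipe)

cfg <- make_default_config("intracellular")  # 9.7-Hz EPSPs, 0.29-Hz LRDs
tr  <- generate_trace(cfg, seed = 1)
ev  <- detect_events(tr)                     # thresholds 0.2 / 3 mV
rbind(event_statistics(ev, cfg$duration, "EPSP"),
      event_statistics(ev, cfg$duration, "LRD"))
```

```
  kind n_events duration_s frequency_hz amp_mean_mv amp_sd_mv decay_mean_ms decay_sd_ms rise_mean_ms
1 EPSP      978        100         9.78    1.941749 0.8125861      40.21172    1.291914      1.93501
2  LRD       21        100         0.21    9.385407 2.8977127     178.01101   56.574370     18.11063
```

The detected unitary background sits at ~9.8 Hz and ~1.9 mV with a
~40-ms decay — the planted study conditions. A single 100-s trace holds
only ~20–30 compound events, so its LRD statistics are noisy (here
0.21 Hz and a decay estimate pulled high by two outlier fits, visible
in the 57-ms SD); averaged over twenty seeds the pipeline recovers the
planted 0.29 Hz / 10.2 mV / 152.5 ms, which is what
`scripts/acceptance.R` computes. Applying a neuromodulator preset and
re-running the same pipeline quantifies its effect:

```r
ne  <- apply_modulator(sim_config(duration = 100, lrd_rate = 0.13),
                       modulator_effect("NE"))
ev2 <- detect_events(generate_trace(ne, seed = 1))
sum(ev2$kind == "LRD") / 100   # prints 0.4: the noradrenergic endpoint
```

The numbered scripts under `analysis/` run the full study workflow
(control event statistics, paired neuromodulation experiments, spectra,
intrinsic properties, MEA network synchrony) and write their tables
under `results/`.

## Layout

```
R/          implementation (generator, detector, kinetics, intrinsic,
            spectral, MEA, graph, statistics, I/O)
analysis/   numbered workflow drivers writing results/
tests/      testthat suite (unit, property and acceptance tests)
vignettes/  methods vignette: models, conventions, design decisions
scripts/    acceptance.R (see above)
```
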