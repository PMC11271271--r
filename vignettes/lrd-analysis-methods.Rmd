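---
title: "Methods: detecting and analyzing large rhythmic depolarizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and analyzing large rhythmic depolarizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrdpipe)
```

## The problem

Intracellular recordings from spontaneously active cortical neurons show
two kinds of depolarizing events: a dense background of unitary EPSPs
(here ~9.7 Hz, ~2 mV, ~40-ms decay) and rare, large compound events —
large rhythmic depolarizations (LRDs; ~0.29 Hz, ~10 mV, ~150-ms decay) —
generated by near-synchronous firing of many presynaptic cells. The
package implements the full analysis stack around these events:
detection and classification, kinetics, intrinsic membrane properties,
wavelet spectra, a multi-electrode-array (MEA) spike/burst/LFP pipeline,
a co-activity-graph synchrony statistic, and a seeded synthetic-data
generator that plants all of the above so every stage can be verified
against ground truth. No recordings ship with the package; all examples
and tests are generated.

## The generative model

`generate_trace()` builds a membrane-potential trace as

* a homogeneous Poisson background of unitary kernels at `epsp_rate`;
* compound LRD events: `lrd_n_components` unitary kernels with onsets
  jittered over `lrd_jitter_ms`, scaled so the composite peak equals the
  drawn amplitude, joined at the composite peak to a mono-exponential
  falling phase with constant `lrd_decay_ms`;
* optional multi-second Up-state plateaus carrying mixed depolarizing
  and hyperpolarizing unitary events;
* optional stereotyped action potentials whenever the noiseless
  depolarization crosses `ap_threshold`;
* additive white Gaussian noise (`noise_sd`, default 0.1 mV).

Three generator choices deserve explanation.

**Kernel shape.** The unitary kernel rises as a difference of two
exponentials and falls, from the peak, as an exact mono-exponential.
The decay statistic reported for real events is the fitted
mono-exponential constant of the falling phase; a pure
difference-of-exponentials has no such constant, so it could never be
"recovered within 1%". Joining an exact exponential at the peak plants
the constant by construction at the cost of a (negligible) derivative
kink.

**Amplitude distributions.** Reported event amplitudes are means over
*classified* events: a 2.0-mV mean for unitary events is a mean over the
class band [0.2, 3) mV. The generator therefore draws amplitudes from
normals truncated to the class band, with the location parameter
calibrated (by root-finding on the truncated-normal mean) so the
realized mean equals the configured one. An untruncated N(2, 1) would
place 16% of "unitary" events above the 3-mV LRD threshold and make the
planted class rates unrecoverable by any threshold classifier. A
consequence is that the realized amplitude SD is smaller than the
nominal `epsp_amp_sd`.

**LRD onset process.** LRD onsets follow a hard-core renewal process
(dead time `min(1 s, 0.5/rate)`, exponential excess, mean rate exact)
rather than a Poisson process. These events are described as rhythmic,
and Poisson onsets at 0.29 Hz would superimpose ~7% of compound events
within a quarter second of each other, making them physically
unresolvable. The unitary background remains strictly Poisson.

Neuromodulation is parameterized by `modulator_effect()`: multiplicative
factors on rates and amplitudes plus a resting-potential shift, with
presets encoding the reported paired endpoints (NE: LRD rate x3,
0.13 -> 0.39 Hz; ACh: LRD rate x0.325, EPSP rate x1.263,
+4 mV depolarization). The printed EPSP factor is treated as inclusive
of any redistributed volley components, so the ACh `desynchronize` flag
changes trace structure only, never rates; applying the `"none"` effect
is the identity and `apply_modulator()` never mutates its input.

## Event detection and classification

`detect_events()` implements the two-threshold semantics (events are
unitary at [0.2, 3) mV, compound at >= 3 mV, measured against a local
baseline) with machinery chosen for one reason: at 9.7 Hz the unitary
events pile up faster than any plain threshold-crossing scan re-arms, so
naive crossing detection undercounts by far more than the Poisson error
of the rates it is meant to recover.

1. **Compound stage.** LRDs are sustained depolarizations: excursions
   of a 150-ms moving average of the baseline-subtracted trace beyond
   the 3-mV threshold (regions closer than 250 ms merge). The amplitude
   is read from a 5-ms-smoothed copy near the envelope peak against the
   median of the 50 ms before onset; regions whose amplitude falls
   short of 3 mV fall through to the unitary stage. Requiring a
   sustained envelope rather than an instantaneous crossing matters:
   chance superpositions of two ~2-mV unitary events exceed 3 mV about
   once per second under the study conditions, and an instantaneous
   rule would multiply the 0.29-Hz compound rate several-fold. Brief
   supra-3-mV deflections without a sustained envelope are therefore
   reported as what they are — unitary superpositions.
2. **Decay subtraction.** Each compound falling phase is fitted
   (profiled mono-exponential, offset fixed at the event baseline) and
   subtracted, because deconvolving a 150-ms decay with a 40-ms
   template leaves residue that spawns spurious candidates.
3. **Candidate stage.** Wiener deconvolution of the decay-subtracted
   trace with the unitary template (regularization `lambda = 5e-5`,
   0.8-ms smoothing) turns each event into a sharp pulse; local maxima
   above half the unitary threshold become candidates. Candidates on a
   compound rising phase — from the 5%-of-amplitude foot to the peak —
   are absorbed into the compound event; candidates on the decay phase
   are kept, per the overlap convention.
4. **Amplitude by template regression.** Each candidate's amplitude is
   the coefficient of its template in a local least-squares model
   (constant + linear trend + a shared exponential tail for superposed
   decays + the templates of all in-window candidates, with negative
   coefficients dropped and refitted). For an isolated event this
   equals peak minus pre-onset baseline; for superimposed events it is
   the only unbiased readout. Candidates below 0.2 mV are rejected.
5. **Second pass.** With the unitary events known, the compound decays
   are refitted on the unitary-subtracted residual and the candidate
   stage reruns on the cleaner trace.

Samples above −20 mV are treated as AP contamination and interpolated
over before any measurement, and events whose span contains such
samples carry `triggered_ap = TRUE`.

### Kinetics

`measure_kinetics()` fits the falling phase of one event from its peak
to the first return to baseline + 10% of amplitude (or the next event
onset) with a profiled least-squares mono-exponential: for fixed tau the
offset and scale are linear, so a one-dimensional search is exact and
derivative-free. Falling phases shorter than 5 samples are flagged
unmeasurable, not errors; poor fits keep their best constant with a low
R-squared.

Inside the pipeline, kinetics are measured with neighbor subtraction
(all other detected unitary templates are removed first), windows are
anchored at the template peak rather than the noisy sample maximum, and
reliability flags are deliberately conservative:

* unitary decay fits are flagged reliable only for events >= 0.5 mV
  (smaller tails sit at the noise floor), with no detected neighbor in
  the symmetric fit window and no compound event within 1 s — criteria
  independent of the constant itself, so ensemble decay statistics stay
  unbiased;
* compound fits skip the first 100 ms after the peak (tails of volley
  components absorbed on the rise contaminate the early decay) and
  must reach R-squared >= 0.95, a meaningful cut at their high
  signal-to-noise ratio;
* the R-squared cut is *not* applied to low-amplitude unitary fits,
  because at fixed noise it preferentially accepts steep decays and
  would bias the ensemble constant downward — the amplitude gate
  replaces it.

### What the recovery tests do and do not show

Over twenty 100-s traces at the default configuration, the pipeline
recovers all six planted statistics (both rates, both amplitude means,
both decay constants) within three standard errors of the ensemble
mean. Two biases are irreducible for any finite-resolution detector and
are visible at larger n: sub-millisecond unitary coincidences merge
(about 1% of events at 9.7 Hz), and background events on compound
rising phases are absorbed by the overlap rule (about 0.7%). The
synthetic traces also idealize real data — stationary rates, a single
kernel shape, white noise, no electrode drift — so passing recovery
here demonstrates correctness of the algorithms under the stated model,
not performance on arbitrary recordings.

## Intrinsic properties

Estimators follow the standard definitions: resting potential as the
mean of a current-free window (drift above 1 mV/s flagged); input
resistance as the least-squares slope of steady-state voltage versus
current over subthreshold steps (steady state = last 20% of the step, a
convention, with AP samples excluded); spike threshold as the argmax of
the centered second difference in the 5 ms before the peak (on a
1-kHz-low-passed copy by default, since raw second differences at
10 kHz are noise-dominated; the unsmoothed estimator remains available);
amplitude as peak minus threshold; half-width between the rising and
falling crossings of threshold + amplitude/2; rheobase as the smallest
current eliciting an AP, with non-monotone series flagged.

## Wavelet spectra

`morlet_tfr()` computes an analytic Morlet transform (center frequency
parameter 6, the standard admissible choice; 64 log-spaced frequencies
over 0.05–100 Hz by default) directly in the frequency domain,
normalized so a sinusoid of amplitude A reads out as A. The trace is
internally decimated (after an anti-alias filter) to eight times the
top frequency to bound the time-frequency workspace. The
baseline-noise reference of `amplitude_spectrum()` is the time-median
wavelet amplitude of a caller-designated event-free segment — the
reference construction is a convention of this package. Band summaries
split at 1 Hz: compound events live below, unitary activity above.

## MEA pipeline

Processing follows the stated constants throughout: zero-phase 2nd-order
Butterworth filters (spike band 300–3000 Hz, corners configurable, the
values themselves being a standard-practice choice; LFP low-pass
100 Hz); spike detection at −5 x MAD/0.6745 per channel with alignment
to the minimum within 1 ms and a 1-ms dead time; firing rate as counts
over duration with the global rate averaged over all channels including
silent ones; burst detection by the network-wide cumulative moving
average of the pooled 5-ms ISI histogram, with the skewness-dependent
alpha of the adaptive CMA method (1 / 0.7 / 0.5 / 0.3 for skewness
< 1 / 1–4 / 4–9 / >= 9 — inherited constants, documented as a
convention) and the 60/140-ms clamps; bursts as maximal runs of at
least three spikes with all ISIs below threshold; LFPs as contiguous
excursions of the low-passed signal beyond 3 SD (computed over the full
channel, no exclusion rule) lasting at least 30 ms, with the signed
extreme as amplitude. The active-channel criterion (rate >= 0.1 Hz) is
a configurable convention.

The synthetic MEA generator plants biphasic negative-leading ~1-ms
spikes on Gaussian noise, with synchronous network events recruiting a
contiguous channel block and adding a negative half-cosine field
deflection. The cholinergic preset replaces the whole drive with
channel-local high-rate bursts: global firing rises about five-fold
while co-activity collapses, reproducing the reported "patchy,
desynchronized" regime. Fixture sizes in the tests (6 x 6 grids,
10–20 s) were chosen so the property suites complete quickly at full
statistical strength; the default configuration remains the 256-channel
16 x 16 lattice at 200-um pitch.

## Co-activity graph and synchrony

`build_coactivity_graph()` bins each channel's spikes into 200-ms bins
partitioning [0, duration) half-open; two channels are connected iff
they both fire in at least one common bin, each edge counted once
regardless of how many bins are shared. All recorded channels are nodes
by default (the statistic divides by the total node count; a channel
mask is available because the choice changes the scale).
`mean_degree_centrality()` returns the formula variant 2E/N by default —
the stated definition, ranging up to N−1 — and a normalized variant
(mean of degree/(N−1), the graph-library convention, ranging to 1).
The two differ by a factor of N−1; the formula variant is the default
and both are reported in summaries, since the printed definition and
the magnitudes usually reported for normalized centrality cannot both
be right. With binary ever-co-occurrence edges the statistic saturates
under dense tonic firing, which is why the synchrony fixtures use
sparse backgrounds; this is a property of the definition, not of the
implementation.

## Statistics

Rank tests wrap the standard implementations with the conventions fixed:
the Mann-Whitney U test is exact for tie-free samples up to n = 8 and
tie-corrected normal otherwise; the signed-rank test drops zero
differences and enumerates all sign assignments exactly up to n = 12
(average ranks under ties — the stock exact path refuses ties); the
2x2 chi-square defaults to no continuity correction, the convention
that reproduces the printed neuron-count comparison (p = 0.0035);
quartiles use linear interpolation (type 7) so box descriptors are
reproducible; samples with n >= 10 get box-plot descriptors with
1.5-IQR whiskers, smaller samples mean +/- SD.

## Numerical choices and limitations

* Seconds and 0-based sample times, half-open windows everywhere.
* Generators restore the caller's RNG state; identical (config, seed)
  gives bit-identical output.
* The truncated-normal calibration solves for the location to 1e-10;
  the profiled exponential fits to a relative tau tolerance of 1e-5.
* The detector's template defaults equal the generator's kernel
  defaults; on real data the template constants should be set from the
  recording (they are ordinary arguments).
* Known limitations: no IPSC/outward-event detection; no spike sorting;
  no phase or coherence spectra; no conductance-based biophysics; the
  Up-state generator plants stylized plateaus, not bistable dynamics.
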