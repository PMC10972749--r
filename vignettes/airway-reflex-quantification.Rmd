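---
title: "Quantifying airway-closure reflexes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying airway-closure reflexes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflexkit)
```

`reflexkit` quantifies a vagally mediated gasping reflex evoked by airway
closure, across three recording modalities: respiratory pressure/flow
traces, two-channel calcium imaging in vagal ganglia, and multiunit
nerve/EMG recordings. This vignette documents the models and rules each
stage implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
conventions adopted where the underlying methodology leaves choices open.

## Conventions

All time windows in the package are half-open, `[start, end)`, and window
membership of a breath is decided by its inspiratory onset; this avoids
double counting across adjacent windows. Breath tables are indexed
contiguously from 1. Cohort percentages are rounded half-up (away from
zero) at one decimal (`pct_of()`), matching the printed precision of
population tallies; integer percentages use `digits = 0`.

## Breath segmentation

Commercial acquisition software assigns breaths with unpublished logic, so
segmentation is implemented here as a transparent, parameter-sparse
procedure:

1. smooth with a centred moving average, `smoothing_window_s = 0.02` s —
   short enough (2% of a 150 breaths/min cycle) not to distort breath
   amplitudes, long enough to suppress sample-level noise;
2. detect inspiratory peaks by **topographic prominence**, requiring
   `prominence_frac = 0.25` of the robust signal range (2nd–98th
   percentile span of the smoothed trace), with a 0.1-s minimum peak
   separation (a 600 breaths/min hard cap);
3. place the inspiratory onset at the last sample at/below the onset
   level before each peak, the expiratory onset at the first baseline
   crossing after it, and the breath end at the next onset. The baseline
   is the median of the smoothed trace; the onset level sits 2% of the
   peak height above baseline so that a slow expiratory recovery that
   hugs the baseline asymptotically is not mistaken for early
   inspiration.

A quantile-range prominence floor was chosen over a MAD multiple: on a
pure sinusoid, 3×MAD (with the usual normal-consistency constant) exceeds
the peak-to-trough prominence and rejects every cycle, and a global MAD
threshold also rejects breaths attenuated 40–60% during compression
epochs because the statistic is dominated by unattenuated breathing. The
quantile-range fraction passes both regimes while still rejecting noise
peaks by an order of magnitude. All thresholds are relative, so
segmentation is invariant to rescaling the signal and equivariant to time
shifts. Degenerate inputs (constant or too-short traces) return an empty
table with a warning rather than an error, so batch pipelines survive
dead channels.

Oesophageal-pressure traces are segmented with the same procedure as
tracheal-pressure traces; this is a convention, as no separate boundary
definition exists for them. Pressure traces carry no volume calibration:
pressure amplitude serves as the volume proxy, and `compute_tidal_volumes()`
(trapezoidal integration of positive flow over the inspiratory phase)
refuses non-flow traces.

## Gasp and sigh calling

A breath is called when its expiratory amplitude exceeds that of **both**
neighbours by more than 50% (`exp_ratio > 1.5`, strict inequality: a
ratio of exactly 1.5 is not a call, and the boundary is tested). The
plethysmography variant additionally requires the inspiratory ratios, as
gasp-like breaths in freely behaving animals are identified from
pneumotachographs by both phases. Each breath is evaluated against its
immediate neighbours independently; two adjacent calls would require each
breath to exceed the other by 50%, which the rule itself precludes, so no
extra suppression logic exists.

The amplitude rule cannot distinguish a gasp from a spontaneous sigh —
context does. Calls inside any epoch's `[start_s, observation_end_s)`
are typed `gasp`, all others `sigh`. Observation windows follow the
stimulus conventions in `stimulus_protocol()`: nebulized stimuli are
watched for 5 min; compression, suction, illumination and inflation use
the stimulus plus 30 s (a package convention where no explicit window is
stated). Baseline normalization divides per-breath features by their mean
over the 10 s immediately before stimulus onset. The Hering–Breuer
quantification reuses that 10-s baseline convention; rates are breath
counts per window, so an apnoeic inflation window yields a normalized
rate of exactly 0.

## Ratiometric calcium analysis

The two-channel reporter expresses GCaMP6 and tdTomato from one
transcript, so the ratio R(t) = GCaMP/tdTomato cancels any multiplicative
factor common to both channels — photobleaching, focus drift, expression
level. ΔF/F₀ = (R − F₀)/F₀ with F₀ the mean ratio over the 20 s before
stimulus onset. F₀ is re-estimated from the 20 s preceding *each* epoch
(tolerating slow inter-epoch drift), while the session-wide ΔF/F₀ trace —
needed because the responsiveness criterion is expressed in units of the
whole-session statistics — anchors F₀ to the first epoch's baseline.

An ROI is responsive to an epoch when its peak ΔF/F₀ over
`[start, end + response_lag_s)` is at least `sd_threshold = 3` standard
deviations above its session mean. `response_lag_s = 5` s extends the
window past stimulus offset to capture offset-peaking transients (the
methodology is silent here; the value is configurable). Two numerical
guards matter:

- the session statistics include stimulus periods, as the criterion is
  stated against "the entire imaging session"; an option to exclude them
  was considered and rejected to keep the implementation faithful to the
  stated rule;
- responsiveness additionally requires the magnitude to be strictly
  above the session mean. Without this, a perfectly flat (zero-noise)
  nonresponder — session s.d. exactly 0 — would satisfy
  `magnitude ≥ mean + 3·sd` vacuously; with it, noise-free synthetic
  sessions are recovered exactly.

Responsive cells are classed by R꜀/Rᵢ, the ratio of peak responses to
compression and inflation: compression-selective above 2,
inflation-selective below 0.5, polymodal between. The stated class
intervals are open, leaving boundary ratios unassigned; boundary values
fall to polymodal, the interior set. Negative peak responses (no response
at all) are floored at 0 before forming the ratio so that a tiny negative
numerator or denominator cannot flip the ratio's sign; the ratio then
saturates at 0 or Inf and classifies correctly. Unhealthy cells —
distinctively bright, unvarying GCaMP — are flagged when the GCaMP
coefficient of variation is below 0.01 **and** the mean exceeds the 90th
percentile of ROI means, and are excluded before scoring.

## Nerve and EMG integration

The hardware integrator used for whole-nerve recordings has an unstated
time constant; the only constant stated anywhere for signal integration
is the EMG value τ = 0.02 s, which is adopted as the default for both and
exposed in `IntegratorConfig`-style arguments. Rectification is about the
**median** rather than the mean, for robustness to spike asymmetry; the
choice is testable (offset invariance holds exactly). The discrete filter
uses `alpha = 1 − exp(−dt/τ)`, so the step response passes through
`1 − e⁻¹` at `t = τ` exactly, which the tests assert. Responses are
percent changes of integrated activity from a pre-stimulus baseline
(default 60 s, configurable — the baseline length for nerve responses is
unstated) and are normalized to the serotonin response over the 100 s
following administration; a nonpositive serotonin response marks the
reference trial unusable and raises an error rather than a sign-flipped
ratio.

## The synthetic-data generator

No raw recordings are deposited for this reflex, so the generator defines
the study conditions under which the pipeline is validated:

- **Breathing**: trains of stereotyped cycles — half-sine inspiration
  (30% of the period) followed by a sharp exponential expiration (decay
  constant 10% of the period) — at 150 breaths/min, 1 kHz sampling
  (pressure-trace acquisition rates are unstated; EMG/ECG sampling is
  1–2 kHz, and 1 kHz is exposed as a parameter), inspiratory amplitude 1,
  expiratory amplitude 0.8 of inspiratory. Gasps and sighs are whole
  cycles scaled by `gasp_gain = 2` — the generator refuses gains ≤ 1.5 so
  injected events satisfy the detection rule by construction, and refuses
  events closer than one breath period. Compression epochs attenuate
  cyclic amplitude by 40–60% (default 50%); epochs can also rescale the
  breathing rate (used for Hering–Breuer simulations, including apnoea).
  Noise is additive white Gaussian — the simplest model that exercises
  the thresholds; coloured noise is deliberately left out.
- **Calcium sessions**: paired ROI×time channels at 2 Hz (volumetric
  two-photon imaging runs at 1.5–3 Hz) over 240 s with compression and
  inflation epochs at 60 s and 150 s; responder ROIs carry
  stimulus-locked transients (1 s rise, 4 s decay, peak ΔF/F₀ = 1) on the
  GCaMP channel only; both channels share one exponential bleach
  envelope, so the ratiometric pipeline must cancel it to machine
  precision; unhealthy ROIs are constant at 3× baseline brightness.
- **Nerve traces**: background Gaussian noise plus random-sign spikes
  (300 spikes/s at 2 kHz) under a multiplicative per-epoch gain envelope,
  so the rectified-integrated mean scales exactly with the stated gain
  and percent-change recovery has a known target (gain 1.5 → +50%;
  serotonin gain 3 → +200%; normalized response 0.25).

Generation is a pure function of its parameters and seed — identical
inputs give bit-identical outputs. What the generator does **not**
emulate: lung biomechanics (no compliance, no pressure–volume coupling),
anaesthesia pharmacology, respiratory rate variability and sigh-preceding
breathing-pattern changes, calcium indicator nonlinearity and saturation,
motion artefacts, and spike-waveform structure. Passing round-trip tests
therefore demonstrates that the quantification rules are implemented
correctly and are robust to additive noise at realistic amplitudes — not
that the detector is validated against the full variability of real
recordings.

## Problem sizes in the test and acceptance suites

The suites validate on 60-s traces at 1 kHz (150 breaths), with 100
seeded replicates for the noisy detection benchmark (10% amplitude
noise); 100-ROI, 240-s calcium sessions with 10 known responders per
stimulus; and 20 seeded 420-s nerve simulations for the normalization
benchmark. These sizes give Monte-Carlo standard errors well inside the
asserted tolerances (e.g. ±0.003 on the normalized nerve response against
a 5% band) while keeping a full run within a few minutes on one core.

## Known limitations

- Segmentation assumes a single dominant respiratory rhythm; it is not
  designed for apneustic or highly irregular patterns beyond the rate
  changes the generator produces.
- The unhealthy-cell filter's CV threshold presumes ongoing fluctuation
  of healthy GCaMP signal; on traces smoothed or averaged upstream it
  would need retuning.
- Tidal volumes require calibrated flow; no pressure-to-volume transfer
  is attempted.
- Stimulus epochs are inputs. The package never infers stimulus timing
  from the trace itself.
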