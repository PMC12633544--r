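---
title: "Emulating a rheostatic closed-loop neurostimulator: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a rheostatic closed-loop neurostimulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheostim)
```

## The control hierarchy

`rheostim` emulates a two-layer ("rheostatic") neurostimulation controller.
The **reactive** layer senses a biopotential, reduces it to a power-in-band
envelope, compares it against a threshold under a timing interlock, and
ramps a constant-current pulse train between a baseline and an active
amplitude. The **feedforward** layer is a 48-slot circadian scheduler that
swaps the entire reactive configuration (sensing montage, filter band,
classifier, policy) twice a day or more — the premise being that biomarker
statistics, and hence correct classifier operating points, differ
systematically between wake and sleep.

Everything per-sample — filters, classifier, pulse engine, and the
sense→classify→stimulate→corrupt-sensing loop of the virtual bench — runs
in compiled code (`src/realtime.cpp`) and is strictly causal: output sample
*n* depends only on inputs up to *n*. This is checked by prefix-equivalence
tests (running the chain on a truncated input reproduces the truncated
output exactly).

## The signal chain and its parameters

| stage | parameter | default | unit | rationale |
|---|---|---|---|---|
| offset removal | `offset_cutoff_hz` | 0.5 | Hz | well below the lowest band edge in use (5 Hz); the device's true cutoff is unpublished, so it is declared, configurable, not inferred |
| band-pass | `band_lo_hz`, `band_hi_hz` | per profile | Hz | biomarker band: beta 13–30, seizure 10–20, gamma 55–65, theta-alpha 5–10 |
| band-pass | order | 4 (fixed) | — | the device chain is a fourth-order IIR; family chosen as Butterworth (maximally flat passband suits envelope tracking, and the device's own motion pipeline is Butterworth) |
| smoothing | `ema_tau_s` | 0.5 | s | EMA coefficient parameterised by time constant, `alpha = 1 - exp(-1/(fs*tau))`, so configurations transfer across sampling rates; the device's coefficient is unpublished |
| output | `quant_uv` | 1 | µV | recorder amplitude resolution |

The band-pass is designed with `signal::butter` and applied as a cascade of
two second-order sections (poles paired by conjugacy, the band-pass zeros
at ±1 split between sections). At the narrowest band in use (5–10 Hz at
630 Hz sampling) the direct-form polynomial is already borderline
ill-conditioned; the cascade keeps each section well-scaled. Tests verify
the cascade against the direct-form filter and against the transfer
magnitude evaluated on the unit circle.

The offset remover is the standard DC blocker
`y[n] = g(x[n] − x[n−1]) + a·y[n−1]` with `a = exp(−2π·fc/fs)` and
`g = (1+a)/2`: zero DC gain, unity gain well above `fc` (at 20 Hz with the
0.5 Hz default the gain is within 0.1 % of one).

**Quantisation** is round-half-away-from-zero to `quant_uv` steps, applied
*after* the EMA (whether the device quantises before or after smoothing is
unstated; quantising last preserves the cleanest envelope for the
classifier). It is opt-in (`power_in_band(..., quantize = TRUE)` and the
loop-recorder path) because microvolt-scale analytic checks of the chain
are sub-quantum.

Filters run causally with zero initial conditions; steady-state assertions
exclude a settling window of five EMA time constants plus filter group
delay, and the tuner excludes the same window from scoring.

## Classifier, debounce and ramp

The classifier enters HIGH at the first sample with envelope ≥ threshold
and returns LOW at the first sample below it — a single threshold, no
hysteresis gap, replicating the seminal single-threshold aDBS design. The
**debounce** (10–120 s on the device; values outside that range warn but
are allowed) is modelled symmetrically: after *any* flip, both transitions
are blocked for the dwell time, and re-crossings during the lock neither
retrigger nor extend it. Whether the real interlock blocks re-entries is
unpublished; symmetric blocking is the simplest reading of "state remains
constant for a minimum period". The initial state is LOW with the interlock
inactive.

The pulse engine runs continuously (at the baseline frequency while LOW,
the active frequency while HIGH — two frequencies are needed because the
epilepsy configuration stimulates at 6 Hz baseline and 126 Hz when
triggered). Each pulse moves the amplitude by at most `ramp_ma_per_pulse`
(0.01 mA default) toward the state's target; ramp-down is symmetric at the
same per-pulse rate, on the grounds that soft offsets are as desirable as
soft onsets. At a state flip the train re-phases so the first pulse of the
new regime lands one pulse period after the flip; consequently a sustained
0.1 → 4.0 mA ramp completes in exactly (4.0−0.1)/0.01 = 390 pulses, 390/126
≈ 3.095 s. SHAM policies keep the amplitude at baseline while producing
identical states and crossing counts — the bookkeeping the device logs is
independent of delivery.

## Scheduler, profiles and the loop recorder

Slots are half-open 30-minute intervals; at most two profiles may be
scheduled (the device's deliberate cap on programming complexity); a
research flag lifts the cap with a log message. Within a profile,
stimulation contacts may not be used for sensing; violations are reported
as data by `validate_profile` rather than thrown, with soft bounds (the
4 mA programmable maximum) flagged as warnings.

Filter and classifier state reset when the **active profile changes** —
profiles may change bands, so carrying filter state across a switch would
be meaningless — while the stimulation amplitude is continuous across
switches (the hardware never snaps the current). Because state resets only
at *changes*, a schedule with identical profiles in every slot is exactly
equivalent to an unscheduled run; an option resets at every boundary for
users who want the conservative behaviour. Whether the real firmware resets
filter state at switches is unpublished.

The loop recorder stores block means of the envelope at
`decimation / fs_base` seconds per value in a ring buffer. Two figures in
the device documentation pin the model: 128 kB holding "up to 100 s" at
630 Hz implies 16-bit words (65,536 samples → 104 s), and the printed
maximum storage period of 1.625 s implies a maximum decimation of 1024
(1024/630 = 1.6254 s). Both are documented inferences, not published
facts. The separately printed "1 sample every 13 min for more than a year
and 8 months" is *not* reproducible under the 16-bit assumption (it gives
about 19.4 months of capacity but requires a decimation far beyond 1024),
so that figure is excluded from the quantitative checks.

**Time compression.** Day-scale experiments run desk-side by letting one
signal second represent `time_scale` wall-clock seconds (slot arithmetic
follows the wall clock; signal dynamics, debounce and time constants remain
in signal seconds, with wall-clock debounces scaled by `1/time_scale` in
the bundled scenarios). The bundled 24-h scenarios use 100× compression
(864 s of signal), chosen so each half-hour slot still spans 18 s ≫ the
envelope time constant.

## What the generators emulate — and what they do not

All generators are seeded; sub-streams are derived deterministically from
the seed and the generator name, so outputs are identical regardless of
call order. The background is `1/f` Gaussian noise (RMS 10 µV by default)
with a slow (~30 s) RMS modulation of depth 0.3 emulating the
nonstationarity of resting recordings. That modulation matters: on a
strictly stationary background, a seizure's broadband power step is
perfectly separable in *any* frequency band, and recovering the diagnostic
band would be meaningless. The depth was fixed once at a level where slow
drift is comparable to, but does not swamp, genuine events.

* **Beta bursts** — 20 Hz sinusoid segments, durations uniform on 0.25–3 s,
  raised-cosine tapers (0.1 s, to avoid spectral splatter leaking into
  neighbouring bands), Poisson onsets thinned by a 48-slot diurnal profile
  that also scales amplitude. The published diurnal curve is not tabulated,
  so the profile is a free 48-vector defaulting to 1.0 by day (06:00–22:00)
  and 0.2 by night with midpoint transition slots placed *inside* the day
  phase, keeping the night uniformly low. Default burst rate 0.15 /s and
  amplitude 30 µV were chosen once as a plausible subthalamic regime
  (day-burst envelopes ≈ 19 µV against a ≈ 3–4 µV in-band floor).
* **Seizures** — a broadband gain (1.3) on the background plus a stronger
  band-limited 10–20 Hz component (12 µV RMS), per-event intensity scaled
  uniformly on 0.7–1.3 so weak events are reliably visible only in the
  diagnostic band; morphology (spike-wave shape) is deliberately not
  modelled because the classifier under test is band-power-based. The
  concatenated layout reproduces the bench preparation of slicing each
  event with 10 s of pre/post signal. An optional day/night profile shifts
  the baseline in-band floor, the phenomenon motivating diurnal classifier
  biasing.
* **Gamma epochs** — 55–65 Hz band-limited noise at 140 µV RMS (so the
  envelope, ≈ 0.8 × RMS ≈ 112 µV, clears the 80 µV device threshold), with
  durations from a truncated normal: mean 8.1 min on [2.9, 11.9] min, SD
  2.25 min chosen so the printed range sits at ≈ ±2.3 SD. Only mean and
  range are published; the truncated normal is the minimal two-sided choice.
* **Theta-alpha events** — oscillations whose instantaneous frequency
  wanders slowly within 5–10 Hz. A tonal (constant-envelope) construction
  was chosen over band-limited noise deliberately: drowsiness theta-alpha
  is rhythmic, and a stable in-event envelope means each event yields one
  debounced crossing, which is what makes "32 events → at most 32
  crossings" a meaningful bookkeeping property.
* **Motion** — gravity baseline plus sensor noise at 100 Hz, movement
  episodes as 0.5–4 Hz band-limited bursts on all axes, optional one-sample
  collision spikes shared across axes, clipped at ±8 g.

Passing tests on these generators show that the *device logic* behaves
correctly under signals with the stated spectral and temporal structure.
They do not show robustness to real LFP phenomena the generators omit:
sleep-stage architecture, spindles, movement and electrode artefacts in the
biopotential channel, impedance drift, or non-Gaussian seizure morphology.

## The virtual bench

Pulse widths (90–100 µs) are far below the 1.587 ms sample period, so each
pulse contributes one signed impulse pair (+, −) on adjacent samples,
scaled by `gain_uv_per_ma × current`; sub-sample pulse shape is
unobservable at 630 Hz. The tank's spatial geometry collapses into that
single gain; the default (2.5 µV/mA) puts a full 4 mA artefact at the same
order as the background RMS — a stress-test regime, and a declared free
parameter since the real artefact amplitude at the sensing montage is not
published. No amplifier blanking is modelled (the montage tolerates
concurrent sensing and stimulation); a gain of zero decouples the loop and
reproduces the open-loop session exactly — by construction, since both
paths share one engine.

A useful structural fact: at 630 Hz sampling, a 126 Hz pulse train lands
every 5th sample exactly, its spectral lines sit at multiples of 126 Hz,
and none fall inside the 10–20 Hz seizure band — so constant-amplitude
high-frequency stimulation barely perturbs that envelope, while the 6 Hz
baseline train has harmonics (12, 18 Hz) inside the band and is the
dominant corruption mechanism. The classifier-degradation report measures
exactly this.

## Tuning

The tuner searches band edges and EMA time constant, scoring each candidate
chain by the PR-AUC of its envelope against **per-sample** labels (a sample
is positive iff inside an annotated window). Per-sample granularity was
chosen for the objective because it is threshold-free and smooth under
small band changes; event-level F1 is reported separately rather than
optimised. PR-AUC uses step-wise interpolation (trapezoids over PR points
are known to be optimistic). The classifier exported with the tuned chain
takes its threshold from the PR point maximising per-sample F1 (clamped
into the declared range) and its debounce from the range's lower bound —
the debounce is a safety dwell, not a detection parameter, so the tuner
does not search it.

The optimiser is a Latin-hypercube initial design (10 points) followed by a
Gaussian-process surrogate (RBF kernel on the unit cube, fixed length-scale
0.3, small nugget) with expected-improvement acquisition over 256 seeded
candidate draws per iteration. The contract is seeded determinism and a
monotone incumbent — the initial design size is independent of the budget,
so a larger budget extends the same evaluation sequence and can only
improve the best score. Grid and random searches are available as
fallbacks. Band-edge geometry: the upper edge is sampled at least 2 Hz
above the lower, so every candidate is a valid band.

A recovered band is judged by *overlap* with the generating band. The upper
edge is only weakly identified — once a band contains the diagnostic
10–20 Hz region, widening it dilutes but rarely destroys the PR-AUC — so
recovery claims concern overlap, not edge-exact identification.

## Numerical choices and degenerate inputs

* Background synthesis FFTs run on 2-3-5-smooth lengths (truncated back),
  avoiding the quadratic worst case of mixed-radix FFTs at awkward prime
  lengths.
* Pulse times accumulate in double precision; mapping pulses onto the
  sample grid guards with a 10⁻⁶-sample epsilon so trains commensurate with
  the sampling rate land on exact sample indices.
* All-zero motion sessions skip peak normalisation and return zeros (the
  documented special case); the motion low-pass is primed with the first
  magnitude value so the session peak is never the filter's own onset
  transient.
* Single-class label vectors: ROC is undefined and errors (no positives) or
  returns `NA` with a warning (no negatives, where the PR side degenerates
  to precision 1); ties in ROC are handled as ½ (trapezoid over tie
  groups), making `roc_auc` exactly the Mann–Whitney pair statistic.
* Ties in greedy event matching break toward the earliest detection.

## Problem sizes

The test suite and the acceptance script run desk-scale versions of the
study conditions, chosen to exercise every code path at comfortable
margins: compressed 24-h days (864 s of signal at 630 Hz), a ~450 k-sample
concatenated seizure set (19 events), two-hour gamma nights, 20 × 150 s
datasets at tuning budget 25 for band recovery, and 10⁴ random draws for
the debounce and comparator-equivalence properties.

## Known limitations

* One biopotential channel; montage arithmetic beyond choosing a sensing
  dipole, amplifier noise, and mains interference are out of scope.
* No electrode-tissue impedance dynamics or charge-balancing
  electrochemistry; compliance is a static current cap.
* The scheduler's clock is idealised (no drift) and strictly 24-hour;
  infradian schedules are not modelled.
* Battery and telemetry behaviour (charging interruptions, streaming) are
  not modelled.
* The bench artefact is a scalar-gain impulse model; it does not reproduce
  amplifier saturation or spatial effects.
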