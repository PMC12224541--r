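---
title: "Models and methods behind synca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synca)
```

`synca` turns multi-ROI fluorescence intensity tables into quantified
synaptic Ca²⁺ events. This vignette explains the models the package fits,
the numerical choices behind them, what the synthetic-data generator does
and does not emulate, and the limitations a user should keep in mind.

## Signal model and normalization

A recording is a per-frame intensity series per ROI, optionally with a
second, Ca²⁺-insensitive reference channel. We model the signal channel as

$$F_i = g_i \, b_i \, F_0 \left(1 + \sum_e a_e\, k(t_i - t_e)\right) + \varepsilon_i$$

where $g_i$ is a multiplicative gain shared with the reference channel
(illumination and focus fluctuations), $b_i$ an optional mono-exponential
bleach, $F_0$ the resting fluorescence, $a_e$ the event amplitudes in
ΔF/F units, $\varepsilon_i$ additive Gaussian noise, and

$$k(t) = \left(1 - e^{-t/\tau_{rise}}\right) e^{-t/\tau_{decay}}$$

the event kernel, normalized to unit peak at its analytic argmax
$t^* = \tau_{rise}\,\ln(1 + \tau_{decay}/\tau_{rise})$.

Single-channel data are normalized as ΔF/F = (F − F₀)/F₀. Two-channel data
are normalized ratio-first: r = G/R, ΔR/R = (r − R₀)/R₀. Ratio-first makes
gain invariance an exact algebraic identity — `drr(g·G, g·R)` equals
`drr(G, R)` to machine precision — rather than an approximation, which is
why the package baselines the ratio and never the individual channels.

**Baselines.** Two first-pass estimators are exposed
(`baseline_spec()`): the mean over a pre-stimulus window (default 0.5 s)
for evoked recordings, and a centered rolling low percentile (default 10th
percentile over 2 s) for spontaneous recordings with drift. A low
percentile of a noisy trace, however, sits below the true baseline by the
corresponding quantile of the noise distribution (≈1.28 σ for the 10th
percentile). That offset inflates every ΔF/F amplitude by several percent
and — more damagingly — leaves a DC offset under decay tails, to which
exponential fits are very sensitive (we measured that a DC error of 1% of
the event amplitude moves the fitted decay constant by roughly 5%). The
mini pipeline therefore re-baselines after the first detection pass:
`rebaseline_eventfree()` estimates the residual baseline as the rolling
*mean* of the event-free samples — an unbiased estimator under zero-mean
noise — and re-references the trace exactly
(`value' = (value − b)/(1 + b)`, the ΔF/F that the corrected baseline
would have produced). For very dense recordings the event mask is shrunk
adaptively until some trace remains event-free; if literally everything is
masked, the trace is returned unchanged rather than guessed at.

## Detection

`detect_peaks()` enumerates strict local maxima (plateaus report their
first sample; boundary samples never qualify, since a local maximum needs
two neighbours), applies the threshold amplitude, a half-prominence-width
filter, and a minimum inter-peak distance resolved greedily by height
(ties go to the earlier peak). These semantics are deterministic and are
tested for exact equality against an independently written brute-force
enumerator on randomized traces. "Peak width" here means width at half the
peak's topographic prominence — the dominant convention — and is a
documented choice, since width conventions differ between tools.

The pipelines (not `detect_peaks()` itself) run detection and all
amplitude/window measurements on a Savitzky–Golay smoothed copy of the
trace (quadratic, 5-sample window; `smooth_trace()`). A quadratic filter
preserves peak height to second order while averaging frame noise. The
raw-sample maximum of a noisy event is biased upward — the argmax picks
the most favourable noise excursion, about +6–10% at noise
SD = amplitude/10 — and the smoothed measurement brings the median
amplitude error under 4% in our round-trip simulations. All kinetic fits
run on raw samples; smoothing only decides *where* to measure and fit.

## Kinetic fits

**Decay.** The model is $y(t) = y_{peak}\,e^{-t/\tau_{decay}}$, fit by
Levenberg–Marquardt least squares (minpack.lm) with t re-zeroed at the
peak and both parameters free ($y_{peak}$ initialized at the observed
peak; $\tau$ at the 10%-return time divided by ln 10). Window placement
matters more than the optimizer: immediately after the peak the rising
phase of the underlying transient is still saturating, so the tail is
locally *slower* than $e^{-t/\tau_{decay}}$, and a fit anchored at the
peak overestimates τ by 10–25% for kernels whose rise is an appreciable
fraction of the decay. The package therefore fits in passes: a first fit
on (peak, 10%-return], then two refits on
$[peak + 0.8\,\hat\tau,\; peak + 4\,\hat\tau]$. The refinement windows are
derived from the fitted constant, not from noisy threshold crossings,
which keeps window placement stable under noise. Windows are always capped
at the event's segment end (the next detected peak), which is what keeps
10 Hz train fits uncontaminated. Residual bias in round-trip simulations
is ≤3% for the slow postsynaptic kernels and ≤1% for fast presynaptic
ones. A free DC offset in the decay model was evaluated and rejected: it
trades offset robustness for a strong τ–offset correlation under noise
that biased the median τ upward by ~10%.

**Rise.** The model is the saturating exponential
$y(t) = a\,(1 - e^{-(t - t_0)/\tau_{rise}})$ anchored near the onset (the
last pre-peak sample below 10% of the amplitude; `find_onset()`). Because
the decay is already underway during the rise, fitting the saturating
exponential alone to the rising samples underestimates τ_rise by 25–45%.
When a decay constant is available, `fit_rise()` therefore fits the full
product form $a\,(1-e^{-(t-t_0)/\tau_{rise}})\,e^{-(t-t_0)/\tau_{decay}}$
with τ_decay held fixed, over a window from just before the onset to past
the peak. Including the peak region anchors the amplitude and removes the
t₀–τ collinearity that otherwise skews short-rise fits under noise; the
fit is started from several initial constants (a 10–90% crossing estimate
plus span-based fallbacks) and the best least-squares solution kept, since
a single poor start can stall in a boundary optimum. Noise-free recovery
at 1 kHz is exact to <0.1%; noisy medians are within ~1%. Rises shorter
than two frame intervals are reported but flagged `near_resolution` — at
115 frames/s a 14 ms rise spans barely two frames and any estimate is
sampling-limited; a fit is attempted whenever the onset-to-peak window
holds at least 3 samples.

**Derived quantities.** `quantify_event()` assembles amplitude (smoothed
peak minus local baseline), sum ΔF (trapezoidal integral from onset to the
10%-return), SNR (amplitude over the SD of the event-free trace), the fit
diagnostics, and provenance (`auto` or `manual`). Events are never
dropped: failed fits propagate `NA` constants plus a flag string.

## Evoked protocols and trains

`stim_protocol()` expands either explicit stimulus times or a
burst descriptor (within-burst frequency, pulses per burst, burst period,
count, start). `partition_evoked()` assigns each stimulus the earliest
unassigned event in the causal window
(stimulus, stimulus + response window]; the window defaults to
min(inter-stimulus interval, 0.5 s) and is clipped with a warning if set
longer. Failures (no event in window) are recorded per stimulus with
amplitude 0 in the per-stimulus amplitude vector, and every stimulus
appears exactly once — a conservation property the tests enforce for the
1 Hz and burst protocols. For trains, `train_amplitudes()` measures each
pulse's response relative to the trace value at the pulse time
(segment-relative), because later responses ride on the decaying tails of
earlier ones; this reproduces closed-form superposition of exponential
tails to within 2% in the tests. `train_summary()` reports per-position
means and the facilitation index (position k over position 1), with
all-failure positions reported as missing, not zero.

## Optical–electrophysiology matching

`match_events()` pairs optical events with mEPSPs one-to-one using an
exact dynamic program over the two time-sorted lists that maximizes the
number of pairs with |lag| ≤ tolerance and, among maximal pairings,
minimizes the total absolute lag. The matching is order-preserving
(non-crossing): for sparse quantal events crossing matches are physically
implausible, and a standard exchange argument shows uncrossing never
reduces the pair count or increases total lag, so the restriction is
lossless — the tests verify exact agreement with an exhaustive
crossing-allowed assignment oracle on all instances up to 12 events. Lag
is measured from the optical event *onset* (falling back to the peak when
the onset is undefined), since the fluorescence peak lags the electrical
event by the rise time; the default tolerance is 100 ms. Detection
fraction is pairs over mEPSP count; paired amplitudes feed a Pearson
correlation (reported absent below 3 pairs or zero variance), and
`ecdf_compare()` provides the two-sample Kolmogorov–Smirnov statistic with
exportable ECDF tables.

## The simulator and what passing tests mean

`simulate_traces()` implements the signal model above literally: linear
superposition of kernels at continuous event times (Poisson or
protocol-driven with latency jitter and failures), per-event amplitudes
fixed or lognormal (parameterized by the median, so median-recovery checks
target the configured value), lognormal per-frame shared gain, optional
bleach, additive Gaussian noise per channel, all driven by one seed
(bit-identical reruns). `simulate_paired()` adds one mEPSP per true event
and deletes each optical event independently with a configured miss
probability. `scenario()` presets carry published single-event parameters
for the supported sensor variants: quantal ΔF/F amplitudes of 0.27, 0.35
and 0.58 with rise/decay constants of 21/99, 14/42 and 14/67 ms for the
three postsynaptic sensors; presynaptic single-AP decay constants of 66.6
and 99.2 ms with 5.3 and 7.0 ms rises; per-sensor optical detection rates
of 57%, 88% and 93%; and genotype mean mEPSP amplitudes of 0.64, 0.38 and
0.82 mV. The presynaptic GCaMP8f ΔR/R amplitude is not published; the
preset uses 0.40 as a representative single-AP value (documented in the
preset's note, and not used by any recovery claim). Scenario defaults fix
the event amplitude at the preset mean (CV 0) and set the noise SD to
one-tenth of the amplitude — the round-trip study condition — with a 20%
shared-gain CV and a noise-free reference channel for the ratiometric
presets.

The simulator emulates: kernel-shaped events with exact ground truth,
baseline drift/bleach, shared-gain artifacts, frame-rate limits, missed
events, and amplitude-scaled mEPSPs. It deliberately does not emulate:
sensor saturation or nonlinearity (superposition is linear), shot noise
(noise is additive Gaussian, independent between channels), movement,
spectral crosstalk, or pixel-level image formation. Passing round-trip
tests therefore demonstrate that the analysis recovers the parameters of
this generative model under realistic noise and frame rates — not that
any particular biological recording satisfies the model.

Problem sizes were chosen to make the statistical checks meaningful while
keeping a full test run around a minute and a half: 200 events per
round-trip scenario (the median of 200 fits has a standard error well
under the 5% recovery band), 100 random traces for the detection oracle,
200 instances for the matching oracle, and 300 events per detection-rate
recovery (binomial CI ≈ ±5.6 percentage points at p = 0.57).

## Numerical choices and degenerate inputs

* Optimizer: `minpack.lm::nlsLM` (Levenberg–Marquardt), 300 iterations,
  ftol = ptol = 1e−12; τ bounded in [frame/100, 100 × recording]. Bound
  hits are reported as failed fits, not as values.
* Ties in detection resolve to the earlier peak; plateaus to their first
  sample. `nearest_peak()` ties resolve to the earlier maximum.
* Flat traces: decay fits flag `fit_failed`/`insufficient_data`; the
  bleach fit reports `no_bleach` when the fitted constant exceeds 10× the
  recording (flat input returned unchanged).
* An event truncated at the recording start has no onset
  (`onset_undefined`); its rise is skipped, the event retained.
* Normalized values below −1 are impossible under a correct positive
  baseline and raise an error instead of propagating.
* The rolling-percentile edge policy is replicate-padding; the first-pass
  percentile's noise offset is handled by the event-free second pass.
* Bleach correction is opt-in and flagged, never automatic, so provenance
  of any amplitude change is always visible.

## Known limitations

* At 115 frames/s, rise constants of ~14 ms and shorter are
  sampling-limited; they are reported with the `near_resolution` flag and
  should be interpreted as upper-bound estimates.
* The measured amplitude at very high frame rates (≥1 kHz) still carries a
  few percent of max-selection bias because the smoothing window is
  frame-based; decay and rise constants are unaffected.
* The event-free rebaselining assumes some inter-event baseline exists;
  recordings with essentially continuous activity fall back to the
  first-pass baseline.
* Mini frequency is detected events over duration; events closer than the
  minimum inter-peak distance merge and are undercounted at high rates.
* The matching tolerance and the onset-versus-peak convention are
  documented defaults, not universal constants; both are configurable.
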