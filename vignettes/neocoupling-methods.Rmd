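---
title: "Methods: burst detection, spike-field coupling and directed connectivity in neocoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst detection, spike-field coupling and directed connectivity in neocoupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neocoupling)
```

# Scope and data model

`neocoupling` analyses paired recordings from a *source* and a *target*
region of the developing olfactory system — canonically the olfactory bulb
(OB) and the lateral entorhinal cortex (LEC) of neonatal mice — and asks
three questions: what oscillatory structure does each region express, how
strongly and at what phase does unit firing couple to it, and in which
direction does activity flow between the regions.

A `recording_session` holds a samples-by-channels LFP matrix in microvolts
with a channel table (region, layer), sorted spike-time vectors per unit,
an optional respiration trace, and labelled `[start, stop)` epochs.
Sessions are stored as a plain-text directory bundle (`meta.json` with a
`schema_version` plus CSV tables), a deliberately boring format: it is
self-describing, language-neutral, human-diffable and needs no binary
dependencies. LFP recorded faster than 1 kHz is decimated to 1 kHz with a
zero-phase anti-alias low-pass before analysis; every rhythm of interest
here lies below 100 Hz, so 1 kHz retains a ten-fold margin.

Two conventions hold throughout. Time is seconds from recording start with
half-open intervals. Instantaneous phase is the angle of the analytic
signal of the zero-phase band-filtered trace, so phase 0 is the
oscillation peak and ±π the trough; neonatal mitral/tufted cells fire at
the trough, i.e. near μ = π in this convention.

# Spectral machinery

Filtering uses 3rd-order Butterworth filters applied forward and backward
(`signal::filtfilt`). Zero phase distortion is not cosmetic: every phase
quantity downstream (spike phases, phase lags) assumes the filter delays
nothing. Power spectra are Welch averages over 4 s Hann windows with 50%
overlap — 4 s resolves the 2 Hz lower edge of the respiration-related
band with eight cycles to spare. Band "area power" is the PSD integrated
over the band, in μV², which by Parseval approximates the variance of the
band-limited component; the tests pin this identity on pure tones and
white noise. Wavelet spectrograms use complex Morlet wavelets of 6 cycles,
a conventional compromise between time and frequency resolution at theta.
Respiration cycles are detected by peak-picking the 1–8 Hz filtered chest
signal with a refractory distance of one eighth of a second; per-cycle
frequency is the reciprocal inter-peak interval.

# Burst detection

The discontinuous theta bursts of the neonatal OB are spindle-shaped:
amplitude-tapered packets of 4–12 Hz activity lasting seconds, recurring
roughly five times a minute, over a near-quiescent background. The
detector works on the smoothed (200 ms moving average) analytic envelope
of the 4–30 Hz filtered trace and uses two thresholds:

* **Core threshold**, mean + 2 SD of the envelope: marks unambiguous
  event cores. Because bursts can occupy a third of the recording and are
  20-fold larger than the background, this threshold is dragged up by the
  events themselves; it is therefore used only to *find* events, never to
  delimit them. Cores shorter than 0.4 s are discarded — noise excursions
  above a 2 SD threshold are brief once the envelope is smoothed over
  200 ms, while genuine events hold the core level for seconds.
* **Boundary threshold**, the median envelope *outside* the padded cores
  (an estimate of the noise floor): each surviving core is extended
  outward to where the envelope falls back to the floor.

Events closer than 300 ms are merged and events shorter than 1 s
discarded. Both thresholds are data-derived, so detection is exactly
invariant to rescaling the signal. The envelope taper means any threshold
crossing truncates a spindle's true support; with the floor at the noise
median the residual duration bias on synthetic spindles is ~5–10%, inside
the 15% recovery tolerance the package holds itself to. On 20 μV-rms pink
noise the boundary estimate is limited by envelope noise around the floor
crossing (rms error ≈ 0.2 s); the event count itself is recovered
exactly.

Relative burst power excludes a 0.5 s guard band around each event when
estimating non-burst power, to avoid envelope bleed. Cross-region burst
co-occurrence counts an event as shared when some event in the other
region overlaps it by at least 60% of the *shorter* event's duration; as
the reference set is a genuine ambiguity, the fraction is reported over
A's events, B's events and their union.

# Spike-field coupling

Locking strength is the pairwise phase consistency (PPC), the mean cosine
of the phase difference over all spike pairs. It is computed through the
algebraic identity PPC = (N·R² − 1)/(N − 1), where R is the resultant
length; the test suite verifies this against the O(N²) definition to
10⁻¹². PPC is used in preference to R or R² because it is unbiased in the
number of spikes — a necessity when comparing units whose spike counts
differ by an order of magnitude — and the suite checks this bias property
directly (mean PPC agrees between N = 50 and N = 500 von Mises samples
while mean R² does not). Significance is a Rayleigh test (Zar's p-value
approximation), α = 0.05, with a minimum of 20 spikes for a significance
call. Theta locking and theta phase-lag analyses are restricted to
detected burst intervals, since theta exists only discontinuously; RR
analyses use the whole trace.

The synthetic generator produces locked trains by thinning a homogeneous
Poisson process with acceptance probability exp(κ(cos(φ − μ) − 1)), which
yields exactly von Mises spike phases. The mean acceptance is
exp(−κ)·I₀(κ), so the base rate is divided by this factor to keep the
realised rate equal to the requested rate at every concentration. The
closed form PPC = (I₁(κ)/I₀(κ))² of the von Mises distribution then
serves as an independent oracle for recovery tests.

# Field-field coupling

Between-region synchrony is measured by the imaginary part of coherency,
Im(Sxy/√(Sxx·Syy)), from Welch cross-spectra. The imaginary part is
exactly zero for any instantaneous linear mixture of one source, which is
what volume conduction produces at these electrode separations; only
time-lagged interaction survives. Significance thresholds per frequency
come from surrogates in which one signal is circularly time-shifted by a
random offset of at least 10 s — this preserves each signal's spectrum
and autocorrelation while randomizing the phase alignment, so the
threshold reflects the distribution of spurious imaginary coherence under
"no consistent lag". Segment-shuffling surrogates were considered and
rejected: a near-periodic rhythm carries the same phase in every Welch
segment, so re-pairing segments fails to destroy its alignment and the
threshold rises to meet the observed value precisely where coupling is
real. All surrogate thresholds in the package use the exact Monte-Carlo
order-statistic convention (the ⌈(1 − α)(n + 1)⌉-th largest of n
surrogate values) rather than an interpolated quantile, whose tail bias
measurably inflates false positives at n = 200.

Phase-lag histograms collect the wrapped difference of instantaneous
phases over (−π, π]; with the phase convention above, a positive circular
mean at the band center means the first signal leads.

# Directed connectivity from spike trains

The standardized spike–spike cross-covariance bins both trains at 1 ms,
counts coincidences at each lag over ±50 ms, subtracts the expectation
under independence (nₐ·n_b/N for N total bins) and divides by the
standard deviation under independence, then smooths with a narrow
Gaussian kernel (SD 2 ms, truncated at ±5 ms) so that single-bin peak
lags remain resolvable. Lag is defined as t_a − t_b: a *negative* peak
lag means the first (source) train leads. Classification follows the
largest significant peak: |lag| ≤ 1 ms is undirected zero-lag coupling
(common drive), 1–10 ms is monosynaptic, 10–50 ms polysynaptic, with
direction from the lag sign. These windows operationalize the
conventional reading of neonatal OB→LEC cross-covariance peaks near
−5 ms and −36 ms.

Significance uses a global band controlling the family-wise error over
lags: the 95th-percentile order statistic of the per-surrogate maximum
|z| under *interval jitter* of the target train — each spike re-drawn
uniformly within its fixed 50 ms window. Interval jitter (rather than
spike-centered jitter) makes the observed correlogram exchangeable with
the surrogates under the null of no timing structure finer than the
window, giving an exact test; spike-centered jitter smooths the
surrogates relative to the null and was measurably anticonservative.
Pairs enter the analysis only if both trains fire above 0.05 Hz
(strictly), the conventional inclusion rule for neonatal units.

# Perturbation quantification

Stimulus effects are quantified per trial against a pre-stimulus window
of the same length immediately preceding onset. Two summaries are used:
the relative change (condition/baseline, so a gain g on the signal
appears as g² in band power) and the optogenetic modulation index
OMI = (p_stim − p_pre)/(p_stim + p_pre), a bounded symmetric contrast
that is exactly antisymmetric under exchanging its arguments — the only
form consistent with reported values near 1 for strong activation and
near 0 for controls. Trial summaries are medians with interquartile
ranges after a single-pass interquartile outlier rule: values farther
than 1.5·IQR from the quartiles (linear-interpolation quartiles) are
removed once, without re-estimating the fences. Note that re-*applying*
the rule to its own output can remove further values in heavy-tailed
data, because the quartiles move; the package treats the rule as
single-pass by definition. Zero-baseline trials are flagged and excluded
rather than producing infinities. "Amplitude" in odor-response tables is
the envelope amplitude of the band-filtered signal; band power is its
square-scale counterpart.

The time-course machinery for pharmacological experiments (per-epoch rate
and power tables, Friedman test with Bonferroni-corrected signed-rank
post hocs against baseline) delegates the tests to the vetted base-R
implementations behind a uniform result type.

# Statistics

The χ² test of equality of two proportions uses pooled-proportion
expected counts with df = 1; Yates' continuity subtraction is applied
only on request, off by default — the printed worked examples (14.67,
10.5, 5.8333, 2.7472) reproduce exactly without correction, and the one
value that requires it (0.38) reproduces with it. The two-sample Kuiper
test uses V = D⁺ + D⁻ between circular empirical distribution functions,
which is invariant under a common rotation of both samples (verified to
10⁻¹²), with a label-permutation p-value. Quartiles use linear
interpolation between order statistics throughout; the outlier rule's
output depends on this choice, so it is fixed and documented.

# The synthetic generator: what it emulates and what it does not

`generate_session()` builds two-region sessions with the statistical
structure the analyses assume, with ground truth attached. Defaults are
anchored to the descriptive statistics of neonatal OB recordings and are
not re-tuned:

| parameter | default | anchor |
|---|---|---|
| RR frequency | 2.37 Hz (±10% slow drift) | median respiration rate |
| RR amplitude | 17 μV | √(2·143.6 μV²) |
| burst rate | 4.7 /min (Poisson starts) | ~4.65 bursts/min |
| burst duration | 4.5 ± 1.5 s, ≥ 0.5 s | seconds-scale durations |
| burst envelope | Hann, 75 μV peak, 8 Hz carrier | spindle shape, ~74 μV amplitude |
| LEC/OB amplitude ratio | 0.76, lag 15 ms | √(112.4/193.4) theta power ratio |
| background | 1/f, 4 μV rms | near-quiescent inter-burst LFP |
| units | 0.2–1 Hz base, ×3–4 in bursts, κ ≈ 1 at μ = π | trough-locked, burst-gated firing |

Overlapping burst events are merged, so the *merged* occurrence is lower
than the Poisson rate (≈3/min at defaults); recovery tests compare the
detector against the merged truth intervals, and the raw Poisson count is
kept as an attribute for calibration tests. Driven LEC units copy source
spikes with probability 0.4 (0.5 in the connectivity recovery
configuration) at a 5 ms (mono) or 36 ms (poly) delay with ≤0.5 ms
jitter.

The generator deliberately does not model: layer-resolved polarity
reversals across a probe (one representative channel per region),
conductance-based dynamics, spike waveforms or sorting artifacts,
non-stationary background (drift, movement), or gamma-band activity
(absent at this age). Passing recovery tests therefore demonstrates that
the estimators are correct and calibrated under the stated statistical
structure — not that they are robust to every pathology of real neonatal
recordings.

# Numerical choices and degenerate inputs

* Stochastic stages (surrogates, the generator) take explicit seeds;
  `run_full_analysis()` derives per-stage seeds from `params$seed`, so a
  bundle is a pure function of (session, params).
* Problem sizes in the test suite: burst recovery uses twenty 600 s
  sessions; cross-covariance null calibration uses one hundred 600 s
  Poisson pairs at 2 Hz; coherence checks use 60 s signals; PPC recovery
  uses 30 replicates per concentration at ~600 spikes each. These sizes
  make the Monte-Carlo standard errors comfortably smaller than the
  tolerances being asserted.
* Degenerate inputs fail loudly and specifically: unsorted spike trains
  name the offending unit, all-zero signals yield empty event lists, a
  zero non-burst power yields a missing relative power rather than
  infinity, fewer than two spikes is an error for phase locking, and a
  flat respiration trace reports "no respiration cycles".
* The null calibration targets of the surrogate tests sit exactly at the
  nominal level (e.g. "95% of frequencies below threshold"), so checks
  against them use the point estimate plus three binomial standard
  errors, the same allowance used for the classifier's type-I error.

# Limitations

The burst detector's boundary precision is limited by envelope noise at
the floor crossing; at 4:1 peak-to-floor ratios boundaries are good to
~0.2 s, which matters if sub-second alignment of burst onsets across
regions is the scientific target. The cross-covariance significance band
assumes no timing structure finer than 50 ms under the null; strong slow
comodulation (shared burst gating) can produce genuine broad correlations
that the jitter null correctly flags as significant but that are not
monosynaptic coupling — classification reads the *lag* of the peak, not
its cause. The imaginary coherence discards genuinely zero-lag neural
synchrony along with volume conduction; that is the price of the measure
and the reason it is reported alongside phase-lag histograms.
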