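---
title: "Methods: luminance-tagging TRFs and texture-segregation VEPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: luminance-tagging TRFs and texture-segregation VEPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumitrf)
```

## The model

A figure texture is split into a foreground region and a background
region whose luminances are modulated independently on every 100 Hz
frame, subject to a per-frame minimum difference of 29.91 cd/m² within
the 4.64–100.94 cd/m² display range, so that the figure remains
segregable throughout the 5 s trial. The EEG at channel $n$ is modeled
as a causal lagged linear functional of each luminance stream $s(t)$:

$$r(t,n) = \sum_{\tau} \omega(\tau,n)\, s(t-\tau) + \varepsilon(t,n),$$

with the temporal response function $\omega$ supported on lags 0–800 ms.
The model's assumptions are (i) linearity in the luminance deviation,
(ii) time invariance within the analysis window, and (iii) additive
noise. Uniform-texture trials carry a single unconstrained stream and
provide a neutral response; subtracting the uniform TRF from the
foreground and background TRFs yields the texture-segregation VEPs
(tsVEPs), which cancel the shared sensory response to luminance and
isolate segregation-specific activity.

## Stimulus generation

The luminance distribution behind the published stimuli is not fully
determined (only the range, the constraint, and near-equal empirical
stream means are known), so the generator draws, per frame, independent
(foreground, background) pairs uniform on the range and rejects pairs
violating the minimum difference. This is the simplest exchangeable law
satisfying every stated constraint, and enforcing the constraint jointly
keeps the two marginals identical, so neither stream is biased relative
to the other. Two properties follow and are asserted in the tests: every
frame satisfies the constraint exactly, and the foreground and
background means are statistically indistinguishable. The constrained
law is *not* the unconstrained uniform — its per-stream mean stays at
the range midpoint (52.79 cd/m²), which differs from the published
empirical means (60.68/60.64 cd/m²); reproducing those would require
reverse-engineering an unstated sampling scheme, which we deliberately
do not attempt. Frames are i.i.d.; no temporal smoothing is imposed.

Session plans fix the probe-trial bookkeeping by exact count:
`round(probe_fraction × n)` trials per condition (21 of 126 at 1/6) are
probes, chosen uniformly, with onsets uniform in 0.25–4.25 s. Exact
counts rather than Bernoulli draws make the nominal probe percentage
reproducible in every session.

## The forward simulator

Ground-truth TRFs are sums of Gaussian bumps over lag — amplitude
(µV per cd/m²), latency (ms), width (ms) — each multiplied by a channel
topography. This family was chosen because the components of interest
are window-localized deflections with regional scalp distributions; it
is not a biophysical claim. The default kernels share a common sensory
response (posterior positivity at ~110 ms, slow rebound at ~220 ms)
across all three conditions and add segregation components matching the
qualitative published pattern: an early (~120 ms) occipital negativity
for the foreground contrast, early and late posterior negativities for
the background contrast, and anterior positivities (late for foreground;
early and late for background).

Convolution is applied to the luminance *deviation* from the adapting
level (the range midpoint). Recorded EEG is AC-coupled and carries no
standing potential proportional to absolute luminance; modelling the
deviation also makes the pre-stimulus driven response exactly zero, so
no artificial onset step is injected into the synthetic recordings. The
estimator is unaffected because stimuli are z-scored before fitting.

Noise is white plus $1/f$ Gaussian noise (default 10 µV SD each,
exponent 1), reflecting the power-law background spectrum of resting
EEG; the $1/f$ component's autocorrelation deliberately stresses the
regularized estimator beyond what white noise would. The default kernel
amplitudes are calibrated once so that the single-trial stimulus-driven
variance is 5% of the noise variance, averaged over the fifteen analysis
electrodes (`measure_snr()` reports ~0.050). Artifact trials (an exact
count at the configured rate) receive a 400 µV, 7 Hz Hann-windowed burst
that passes the 1–40 Hz analysis band, so threshold rejection sees it
after filtering; behaviourally incorrect trials are flagged by exact
count as well. The default exclusion rates (10% artifacts, 8% incorrect)
keep retained trials comfortably above the study's floor of 82 per
condition.

What the simulator does **not** emulate: ocular and myogenic artifacts
with realistic spatial structure (hence the preprocessing chain has no
ICA stage — a threshold is the only rejection rule), volume-conducted
correlated noise, nonstationarity across a session, and nonlinearities
such as luminance adaptation or saturation. Passing tests therefore
demonstrate correctness of the estimation and statistics machinery under
the stated linear model, not robustness to every failure mode of real
recordings.

## Preprocessing

The chain mirrors standard epoch-based practice: order-2 Butterworth
band-pass 1–40 Hz, re-reference to averaged mastoids (TP9/TP10),
epoching −1000 to 7000 ms with baseline −1000–0 ms, rejection of epochs
exceeding ±100 µV on any channel or flagged incorrect, decimation to
100 Hz, and cropping to 500–4500 ms (400 samples) to discard onset and
offset transients. Numerical conventions, each stated because the
alternative is defensible:

* **Zero-phase filtering** (`signal::filtfilt`): no group delay, so
  component latencies are preserved, at the cost of doubling the
  effective order. A causal filter would shift the windows.
* **Strict threshold**: "exceeds ±100 µV" is read as a strict
  inequality; an epoch peaking at exactly 100 µV is retained.
* **Decimation by subsampling**: the 40 Hz low-pass edge is below the
  new 50 Hz Nyquist, so no extra anti-alias filter is applied. The
  order-2 rolloff is gentle (~47% amplitude remains at 50 Hz), so some
  40–80 Hz noise aliases into the band; this is a property of the
  published filter design, accepted as-is, and the filter tests assert the
  analytic Butterworth magnitude response rather than an idealized
  brick wall.

## TRF estimation

Stimuli and EEG are z-scored over the concatenation of retained trials
before fitting (the published account says only "normalized"; z-scoring
is the convention that makes an intercept-free identity-penalty ridge
appropriate). Each trial contributes an independent design block of
lagged stimulus copies on the 0–800 ms grid; ridge weights solve
$(X^\top X + \lambda I)\,w = X^\top y$ with $\lambda = 1$.

One normalization subtlety is load-bearing. The tsVEP is a *difference*
of TRFs from different conditions, so the two TRFs must be in identical
units. Scaling each condition by its own statistics breaks this: the
minimum-difference constraint inflates the figure streams' marginal SD
about 7% above the uniform stream's, so under a true null (identical
kernels) per-condition scaling leaves a systematic residual in the
subtraction and inflates the false-positive rate of the component tests.
The pipeline therefore computes one set of normalization
constants per subject, pooled across all conditions
(`pooled_normalization()`): one stimulus scale (all streams are
luminance in cd/m²) and one scale per EEG channel.
`normalize_concatenated()` retains the per-condition form for standalone
use, and `estimate_condition_trfs()` accepts either.

Two estimation decisions matter most:

* **Joint stream estimation.** The minimum-difference constraint
  anticorrelates the foreground and background sequences (r ≈ −0.6), so
  fitting them separately would alias shared variance into both kernels.
  By default both lagged designs sit side by side in one regression;
  `estimator_config(joint_streams = FALSE)` provides the separate-fit
  variant for comparison.
* **Full within-trial stimulus history.** The analysis window starts at
  500 ms but lags reach 800 ms, so the design's first rows need stimulus
  samples from before the window. Designs are therefore built from the
  full trial stimulus and the rows subset to the analysis window;
  zero padding applies only before stimulus onset, where the luminance
  deviation truly is zero. (Building the design from the cropped
  stimulus instead biases the joint fit badly — with the correlated
  streams, noiseless recovery correlation drops to ~0.4 — which is why
  the package treats the full history as part of the contract.)

The shuffle null re-estimates the TRFs after permuting the
trial-to-sequence pairing by a random *derangement*, so no trial keeps
its own sequence; anything short of that leaves veridical pairs in the
null. Since shuffled stimuli are independent of the EEG, the shuffled
TRF estimates the pure noise floor of the estimator.

Estimated kernels are reported and evaluated as cohort grand averages,
the form in which TRF and tsVEP waveforms are published. At the
calibrated operating point the per-subject estimate carries a per-weight
noise floor of roughly $\sigma/\sqrt{N}$ ($N$ = trials × samples), which
bounds single-subject kernel correlations near 0.8 regardless of
implementation quality; averaging across a cohort reduces the floor by
$\sqrt{n_{subjects}}$ and is what the recovery, shuffle and leakage
checks measure.

## Statistics

Component amplitudes are means over a region's three electrodes and over
the lag samples whose centers fall in the window *inclusive* (100–140 ms
at 100 Hz spans exactly 5 samples). One-sample t tests are two-sided
against zero with Cohen's $d = t/\sqrt{n}$ (the identity is asserted at
machine precision on every reported row). The Bonferroni family is the
five regions scanned within each contrast × window — the published
account states the correction but not the family, so the family size is
explicit and configurable.

The 2 × 5 repeated-measures ANOVA runs through the multivariate
linear-model route (`car::Anova`, type III) behind a stable interface;
Mauchly's test is evaluated for every effect with more than one
numerator df and the Greenhouse–Geisser corrected p-value replaces the
uncorrected one when Mauchly rejects at 0.05 (`gg = "always"`/`"never"`
force either behaviour). Two-level effects are spherical by
construction ($\varepsilon = 1$). Partial $\eta^2$ is
SS$_{effect}$/(SS$_{effect}$+SS$_{error}$). Simple effects of stimulus
within region are computed as squared paired t statistics, identical to
the two-level repeated-measures F; the identity is asserted internally.
An independent textbook sums-of-squares decomposition serves as the
oracle in the test suite, so the library route and first principles are
checked against each other rather than collapsed into one call.

Degenerate inputs are errors, not silent results: zero-variance
channels or streams, zero-variance t-test samples, missing ANOVA cells,
empty post-rejection epoch sets, and single-trial shuffle requests all
raise classed conditions.

## Problem sizes and reproducibility

The validation suite runs at desk scale, chosen once: constraint checks
over 10⁵ frames; kernel recovery over 20 simulated subjects × 100 figure
trials; the shuffle control over 22 subjects × 126 trials (the study's
nominal cohort and trial counts); type-I error over 500 null cohorts of
6 subjects × 12 trials/condition with an occipital-only montage, where
the foreground kernel is set equal to the uniform kernel and the early
occipital window is tested at $\alpha = 0.05$; and large simulations run
directly at the 100 Hz analysis rate, while the preprocessing chain is
exercised end-to-end at 1000 Hz on smaller sessions. A single master
seed derives every per-subject and per-trial seed through a Lehmer-style
hash, so any sub-computation can be regenerated in isolation and a full
pipeline run is byte-reproducible, manifest included. Domain objects
serialize to schema-versioned JSON containers with lossless numeric
round-trip.

## Known limitations

* The synthetic luminance law cannot reproduce the published empirical
  stream means (see above); stimulus-level acceptance is limited to the
  constraint and range.
* Published amplitude/t-value results derive from non-public human
  recordings and are not reproducible here; the statistics are validated
  by construction (oracles, identities, type-I calibration) instead.
* λ is fixed at 1 as published; no cross-validation is provided.
* The ANOVA interface targets the balanced complete 2 × k
  within-subject design only; no imputation for missing cells.
* EDF/BrainVision import is out of scope; user-supplied epochs enter
  through the documented array container.
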