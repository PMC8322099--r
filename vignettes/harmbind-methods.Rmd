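---
title: "Methods: coincidence-dependent harmonic integration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coincidence-dependent harmonic integration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmbind)
```

harmbind implements the computational pipeline used to study how auditory
cortex binds multi-frequency sounds whose components start together.
Harmonic sounds — stacks of integer multiples of a fundamental frequency
(F0) — dominate rodent vocalizations, and the binding of their components
into one perceptual object depends on onset synchrony: shifting the onset
of half the components by a few tens of milliseconds breaks the percept.
The package covers the full chain: stimulus construction, F0 extraction
from vocal recordings, single-cell calcium-imaging statistics,
population-level ensemble analysis, noise-correlation subnetwork
detection, spike-train and optogenetic-suppression analysis, and
behavioral psychometrics — together with synthetic-data generators that
plant known ground truth for every stage, so each estimator can be
validated by recovery.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic benchmarks do and
do not establish about real data.

## Stimulus model

A stimulus is a list of tone components (frequency in Hz, onset and
duration in ms, 5 ms linear rise/fall ramps by default), occupying
half-open intervals `[onset, onset + duration)`. Harmonic stacks place
components at exact integer multiples `k * F0` up to a ceiling (default
40 kHz), so a 4 kHz stack holds ten tones. Onset shifts (Δonset, in
−45…45 ms steps of 15 ms) are applied either to the lower half of the
components (`floor(n/2)` lowest; this makes odd counts well defined) or to
the fundamental alone. The shift is additive on the designated group and
zeroes the rest, so shifting by Δ and then −Δ restores the original
stimulus. Inharmonic controls add independent uniform jitter in
`[−0.5 F0, +0.5 F0]` to each component under a recorded seed, so the same
frequency set can be reused across onset shifts; a jittered frequency that
falls at or below 0 Hz is redrawn (preserving the component count) unless
rejection is requested.

Waveforms are sums of sine-phase components with equal per-component
amplitudes, scaled so the coherent peak (the sum of component amplitudes)
equals a configurable full-scale reference. Sound-pressure levels in dB
are carried as labels only: software has no calibrated transducer, so the
0 dB reference is a full-scale sine of amplitude 1. An alternative mode
interprets per-component levels as relative dB, for the reading of
"equal level" as equal dB rather than equal amplitude; equal amplitude is
the default. Presentation schedules are blocked: each block is an
independent seeded permutation of all stimuli, five blocks by default.

## Vocal F0 extraction

Syllables are detected where the amplitude envelope (block maxima of
|x| at 0.25 ms resolution) exceeds 10 baseline SDs; bounds extend to the
5 SD crossings and 15 ms margins are kept. The baseline SD comes from a
leading segment of the recording (default 100 ms) assumed event-free;
bursts whose margin-extended intervals overlap are merged.

Each syllable's spectrogram (Hann window of twice the time bin; 1 ms bins
by default, 0.5 ms for faster calls) is processed per time bin by
moving-average subtraction along frequency (4 kHz window), a 3×3 median
filter, and an optional ridge (vesselness) enhancement before thresholding
at 5% of the syllable maximum. The ridge filter is a standard
Hessian-eigenvalue vesselness over pixel scales 1–3 with blobness constant
0.5; because its scale-space smoothing can bridge neighboring harmonics,
its mask is intersected with the power mask rather than replacing it, and
it can be bypassed entirely. Connected components (flood fill) shorter
than 7 ms are rejected.

Component frequencies are refined per time bin by quadratic interpolation
of the log spectrum around the contour peak. The raw pixel position
quantizes frequency at the bin width (500 Hz at 1 ms bins), which is far
coarser than the 50 Hz F0 grid; parabolic refinement of a windowed
sinusoid is accurate to a few Hz at the signal-to-noise ratios of
interest, and `refine = FALSE` restores the pixel-position behavior.

F0 is estimated per 1.4 ms segment by harmonic template matching. For
observed component frequencies `F_i` and candidate F0, each component gets
harmonic order `k_i = max(1, round(F_i / F0))` and the evaluation function
is

$$\mathrm{EF}(F_0) = \sqrt{\tfrac{1}{n}\sum_i \left(\tfrac{k_i F_0 - F_i}{F_i}\right)^2},$$

minimized over a grid (default 1–10 kHz in 50 Hz steps, spanning the vocal
range at a resolution finer than its spread). A segment with EF below 0.5
is judged harmonic. Two choices deserve note. First, the sum runs over
observed components, not template orders, so missing harmonics are not
penalized; two components rounding to the same order both stay in the sum.
Second, EF ties exactly across subharmonics — every divisor of a
fundamental reproduces its lattice — so the grid minimizer breaks ties
toward the largest F0, which recovers the true fundamental. The remaining
ambiguity (a stack containing only even orders) is unresolvable from the
observed components alone. Because the Hann mainlobe is about 2 kHz wide
at 1 ms bins, harmonics of fundamentals below ~2 kHz are not separable at
the default resolution; the synthetic vocal generator therefore plants
F0s at or above 2 kHz.

F0 usage is summarized as a probability-normalized histogram with the
10th/50th/90th percentiles (the central 80% interval and median).

## Calcium-imaging statistics

Cell traces are neuropil-corrected as
`F = F_cell_measured − 0.9 × F_background`, and only ROIs at least 3%
brighter than their background ring are kept. ΔF/F uses a per-trial
baseline mean F₀ (window: 1 s before sound onset; the baseline length is a
configuration choice, stated here once) and a 20 a.u. offset added to the
denominator as a guard against near-zero baselines. Response amplitude is
the trapezoidal area under the baseline-subtracted ΔF/F during 1 s after
onset (ΔF/F·s); a charge mode integrates sign-flipped negative-going
current over the sound duration for voltage-clamp data.

A cell–stimulus pair is significantly excited only if ΔF/F exceeds
`k × SD(baseline)` consecutively for at least 0.5 s in more than half of
the trials **and** in the trial-averaged trace. The SD multiples default
to 3.3 (pyramidal), 1.6 (SOM) and 2.6 (PV); `calibrate_threshold()`
reproduces the calibration — the largest threshold retaining a 90%
true-positive rate on labeled tone responses, i.e. the 10th percentile of
the positive class (gap midpoint under perfect separation; boundary with a
warning when the target is unattainable). A perfectly flat baseline
(noiseless synthetic input) degenerates to threshold 0, under which an
all-zero response is not significant and any sustained positive response
is; this keeps noiseless ground-truth sessions flowing through the same
code path.

The coincidence-preference index is `CI = (C − S)/(C + S)` between the
coincident-harmonics amplitude C and a shifted-harmonics amplitude S,
computed only where the coincident and/or the shifted response is
significant; negative amplitudes are clipped to 0 first, bounding CI in
[−1, 1], and a pair that is 0/0 after clipping is an undefined sentinel
dropped from pooling (counts retained). CIs for ±15 and ±30 ms shifts are
pooled per area; ±45 ms is excluded. The linearity index
`LI = (H − S)/(H + S)` compares a multi-tone response H with the linear
sum S of its component-tone responses under the same clipping; imaging
analyses keep LI per Δonset, while the whole-cell (charge) mode averages
LI across the ±15/30 ms shifts before comparing against coincident LI.

Pure-tone tuning: the threshold intensity is the lowest level with a
significant response; CF is the strongest-response frequency there. When
the threshold sits at the lowest tested level, CF averages two estimates
at that level — the peak frequency and the mean of a least-squares
Gaussian over log2 frequency (positivity-bounded, Levenberg–Marquardt).
BW70 averages the octave span of significant responses at 70 dB and the
span where the 70 dB Gaussian fit exceeds half its peak; the fit threshold
is a package choice, as is the whole fit parameterization.

## Ensemble geometry and clustering

The population matrix is conditions × ROIs: nonsignificant amplitudes are
zeroed (de-noising), each ROI is normalized to its maximum across Δonset
conditions, and only ROIs significant in at least one condition enter
(all-zero normalizers are excluded and counted). PCA treats conditions as
observations (mean-centered, no scaling). Pairwise condition geometry uses
Euclidean distances divided by `sqrt(N_ROI)` — making values comparable
across population sizes; duplicating every column leaves them unchanged —
and Pearson correlation across ROIs, with per-condition means excluding
the diagonal.

Response profiles are clustered by non-negative matrix factorization of
the conditions × pairs matrix with k = 3, Frobenius multiplicative
updates, and 100 random nonnegative restarts under a master seed that
spawns per-restart seeds (so the best-of-restarts error is non-increasing
in the restart count). Each ROI–sound pair joins the cluster of its
dominant coefficient; a dominant fraction below 0.5 is labeled "others".
Templates are identified as negative-shift / positive-shift / coincidence
by the Δonset at their maximum, with ties broken toward coincidence. The
cluster count is fixed at three; profiles from several F0s (and areas) are
concatenated so a cell can be, say, coincidence-preferring at one F0 and
shift-preferring at another. The coincidence fraction per area counts
coincidence pairs over all clustered pairs including "others" (a flag
switches the denominator), with a chi-square test for two groups.

Cluster-membership overlap across F0s is tested by permutation: observed =
cells in ≥ 2 membership sets; the null redraws each set uniformly over the
cell universe preserving set sizes (stratified per mouse when strata are
given); `p = (1 + #(null ≥ observed))/(1 + n_perm)`, which is valid and
strictly positive. The overlap count is integer-valued, so attainable
p-values form a lattice; calibration checks of this estimator are only
informative when the null spread is wide enough that the lattice spacing
is small relative to the test's resolution, which is how the test-suite
null configuration (universe of 1000, five sets of 150) was chosen.

## Noise correlation and matched controls

Noise correlation subtracts each ROI's per-stimulus mean amplitude,
concatenates the residuals across stimuli and trials, and takes Pearson
correlations per simultaneously recorded pair; adding per-stimulus
constants changes nothing, and zero-variance residuals yield sentinels.
Distance-matched controls draw, per target pair, three random same-field
pairs within ±10% of the target distance (the tolerance doubles up to
twice on failure, then the pair is dropped or an error raised per the
strictness flag). SD- and SNR-matched controls find, for each ROI of a
pair, the two ROIs with the closest statistic (baseline ΔF/F SD, or peak
evoked amplitude over SD) — the two sets kept disjoint so the 2 × 2 cross
combinations are four valid control pairs. All control sampling is
seeded.

## Spikes, suppression, and behavior

PSTHs use uniform half-open bins (10 ms default), trial-averaged rates,
optional baseline subtraction (0–200 ms before sound), and an optional
3-bin moving average kept separately for display and never used in
quantification. Evoked magnitude is the positive-going bin sum in
0–150 ms, optionally normalized to the maximum control response.
Optogenetic suppression kinetics are fit on a 0.5 ms PSTH normalized to
the 10 ms pre-LED rate with `r(t) = 1` before a latency and
`floor + (1 − floor) · exp(−(t − latency)/τ)` after it; the latency is
profiled over a 0–20 ms grid with the inner (floor, τ) fit by bounded
Levenberg–Marquardt, and non-decaying input (late rate above 0.8) returns
a failure sentinel. Latency and τ trade off in noisy data — a latency-0
fit with inflated τ can shadow the true curve — so τ recovery is
validated statistically (within 25% at 500 trials of a 50 Hz multiunit)
rather than per-trace.

Behavioral sessions (go/no-go lick discrimination of coincident vs
onset-shifted harmonics) are fit with a logistic on the log-modulus scale
`x = sign(Δ)·log10(1 + |Δ|)` (base 10, +1 inside — the transform is
symmetric and keeps 0 at 0) by binomial maximum likelihood (`glm`). The
half-max Δonset back-transforms the fitted midpoint; degenerate all-lick /
no-lick sessions return sentinels. Sessions are trimmed of leading and
trailing runs of ≥ 10 consecutive misses on target trials (unmotivated
blocks) and capped at the first 250 trials by default. Optogenetic
broadening is `(half_max_LED − half_max_control)/half_max_control`,
computed per session and then averaged: group-mean arithmetic on the two
thresholds is not the same quantity and gives a smaller number, so the
per-session aggregate is reported alongside, never asserted against, the
group-mean version. d′ is the equal-variance Gaussian `z(hit) − z(fa)`
with rates clipped at a configurable bound (conventionally `1/(2N)`); the
formula choice is the package's, stated here once.

## Synthetic ground truth

`generate_population()` plants, per trial, a response amplitude
`w(Δonset) · peak · (1 + cv·ε) + N(0, σ_n) + latent`, where `w` is an
archetype tuning profile (coincidence peaking at Δ = 0, shift archetypes
saturating on one side, nonresponsive all-zero), and the latent term is
shared within each same-F0 coincidence subnetwork on every trial, giving
the closed-form pairwise noise correlation
`r = σ_l²/(σ_l² + σ_n²)` when the multiplicative term is off. Amplitudes
are rendered with a difference-of-exponentials calcium kernel (rise 50 ms,
decay 1 s — GCaMP6s-like; the tracer kinetics are not part of the analysed
study, which consumed measured traces), truncated at 4 s and normalized to
unit trapezoidal area over the 1 s readout window so the AUC readout
returns planted amplitudes exactly in the noiseless limit. Background
(ring) traces carry independent noise and are mixed into the measured cell
trace with the same 0.9 coefficient the correction subtracts, so neuropil
correction is exercised nontrivially. Same-F0 coincidence subnetworks are
planted as 2-D Gaussian spatial clusters (SD 60 µm) in a 620 × 620 µm
field; all other cells are uniform. Defaults: 5 trials per stimulus
(blocked schedule), 30 Hz frames, 6 s trial spacing, peak amplitude
0.5 ΔF/F·s, multiplicative cv 0.2, additive amplitude SD 0.05, latent SD
0.033 (r ≈ 0.3), trace noise 1 a.u. on a baseline of 100 a.u.

The other generators plant harmonic syllables with silent gaps and white
noise at a stated SNR (with a leading noise-only segment so the detector
can estimate its baseline); inhomogeneous Poisson spike trains whose rate
is multiplied by the suppression model on LED trials; and Bernoulli lick
outcomes from the log-modulus logistic with a shifted midpoint on LED
trials (30% of trials by default). Every generator is bit-reproducible
under a fixed seed.

What the recovery benchmarks show — and do not. Passing them establishes
that each estimator inverts its own generative model at realistic noise:
planted amplitudes, CIs, cluster labels, correlations, τ and psychometric
midpoints come back within stated tolerances. They do not certify
performance on real recordings, where neuropil contamination is
structured rather than white, calcium transients are nonlinear in spike
count, response variability is heavier-tailed and nonstationary, running
and arousal modulate correlated variability, and vocal syllables have
frequency-modulated contours rather than stationary harmonics. The
generators emulate the statistical skeleton of those data, not their
physics.

## Problem sizes and numeric conventions

The test suite and the acceptance script run deliberately scaled-down
study conditions: two to five F0s with 6–16 cells per archetype per F0
(the study's cell–F0 pair counts are in the hundreds), 26-syllable vocal
recordings (~1000 harmonic segments), 20 clustering seeds at archetype
SNR 3, 200 permutation-calibration simulations of 1000 permutations, 50
psychometric sessions of 250 trials, and 500-trial suppression fits —
sizes at which every recovery criterion is statistically decidable in
minutes on one core. Integration is trapezoidal throughout; EF ties break
to the largest F0; NMF restarts stop on a relative error change of 1e−7
or 500 iterations; undefined values (0/0 indices, zero-variance
correlations, failed fits) are `NA` sentinels excluded from summaries
with counts retained, never coerced to 0. All randomness flows through
explicit integer seeds below 2³¹.
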