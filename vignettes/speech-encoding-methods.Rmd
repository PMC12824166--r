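---
title: "Methods: high-gamma speech encoding analysis on synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-gamma speech encoding analysis on synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`speechenc` implements the analysis chain used to characterize
speech-evoked activity in intracranial (ECoG) recordings: extraction of
the high-gamma (70–150 Hz) analytic amplitude, trial-aligned
responsivity statistics, onset-latency detection at 1-ms resolution,
Gaussian-mixture spatial clustering of electrode coordinates,
spectrotemporal and semantic receptive-field estimation by normalized
reverse correlation (NRC), and modulation-domain tuning comparisons.

Patient recordings of this kind are restricted-access, so the package
ships a synthetic-data generator that reproduces the statistical
structure each stage assumes — a linear spectrotemporal drive plus
noise, a repeated-sentence trial protocol, planted onset latencies,
spatially clustered electrode coordinates, and word streams with
per-word embedding vectors. Every stage is therefore testable against
planted ground truth, end to end, without any external download.

# The synthetic study protocol

The default protocol mirrors a passive-listening block: ten unique
sentences, each presented ten times in random order, separated by
one-second silent gaps; sentences last a few seconds. `synth_config()`
holds these constants, and `synth_spectrogram()` lays out the full
presentation sequence as a bands × frames spectrogram at 100 frames/s
with exactly-zero gap columns.

**Stimulus texture.** Each unique sentence is broadband noise shaped by
eight random spectrotemporal ripples: the value in band $b$ at frame
$t$ is $\exp\{1.2\,\rho(b,t)\}\,(z_{bt}^2 + 0.05)$ with
$z_{bt}\sim\mathcal N(0,1)$ i.i.d. and $\rho$ the mean of the ripples
(drift rates 1–12 Hz, densities 0.1–1.5 cycles/octave, random phase
and direction). The ripples give the stimulus a non-trivial
spectrotemporal autocorrelation, as natural speech has; the chi-square
point statistics are heavy-tailed like speech power. The heavy tail
matters for estimation: the silent gaps induce a strong "stimulus on"
common mode in the lagged autocorrelation matrix, and a heavy-tailed
within-sentence texture keeps the informative eigenvalue bulk well
above the relative tolerances used by the NRC fit. This is synthetic
texture, not resynthesized speech: real audio enters through
`cochlear_spectrogram()` and the TIMIT-style annotation reader, and
conclusions from passing tests transfer to real data only insofar as
real speech spectrograms are also full-rank and roughly stationary
within sentences.

**Band axis.** 64 bands log2-spaced from 180 Hz to 7 kHz by default.
The bottom band sits above DC so that octave spacing (and hence
cycles/octave) is well defined.

**Words.** Each unique sentence is tiled from its onset with 2–6
non-overlapping words with durations uniform on 200–600 ms (frame
aligned), drawn from a default vocabulary of 200 word types. Synthetic
embeddings (`synth_embeddings()`) are i.i.d. Gaussian unit vectors —
a pluggable stand-in for an external word-vector table; real
embeddings can be supplied as any matrix with word types as rownames.

**Ground-truth receptive fields** are separable Gabors
(`make_gabor_strf()`): a Hann-windowed temporal sinusoid (rate in Hz)
times a Gaussian-windowed sinusoid in log2-frequency (density in
cycles/octave). Their modulation coordinates are known analytically,
so the modulation transfer function (MTF) peak location is a planted
oracle. `simulate_highgamma()` convolves a Gabor with the stimulus and
adds white Gaussian noise scaled so that the signal/noise variance
ratio matches a requested SNR (10 dB by default, i.e. a prediction
ceiling of $\sqrt{\mathrm{SNR}/(1+\mathrm{SNR})} \approx 0.95$).

# Preprocessing

`hilbert_highgamma()` band-passes 70–150 Hz with a 4th-order
zero-phase (forward–backward) Butterworth filter, takes the analytic
amplitude of the FFT-based analytic signal, anti-alias filters and
resamples to 100 Hz. `morlet_highgamma()` instead averages the
magnitudes of eight 7-cycle complex Morlet wavelets log-spaced across
the band and resamples to 1000 Hz for the 1-ms latency analysis. The
filter family, order, wavelet count and cycle number are package
choices — common defaults in the ECoG literature; agreement between
the two paths (r ≥ 0.9 on band-limited carriers with slow envelopes)
is part of the test suite, and quantitative accuracy is defined
against closed-form envelopes, not any legacy implementation.
`zscore_block()` standardizes each electrode by its full-block mean
and SD, silences included; the first/last 250 ms of the envelope
blocks are flagged (attribute `edge_ms`) as filter transients.
Electrode rejection is a simple robust rule (SD > 5× the median SD).

# Responsivity statistics

Trials are aligned to sentence onsets with a 500-ms pre-onset
baseline. For each post-onset bin, the repeats' values are compared
against the pooled baseline (all repeats × all baseline bins of that
sentence) with a two-sided Wilcoxon rank-sum test using the normal
approximation with tie correction. Pooling the baseline is a
deliberate choice: with ten repeats, a bin-vs-same-bin comparison has
almost no power, while the pooled null sample is large and stable.

Per sentence, p-values are Bonferroni-corrected for the number of
post-onset bins. An electrode is *responsive* if any bin of any
sentence survives correction; `is_responsive()` applies a further
Bonferroni factor over sentences so that the per-electrode family-wise
error is controlled at the nominal level (bins × sentences in total).
Response magnitude is the mean z-value over significant bins, averaged
over sentences with significant bins — one of several defensible
summaries; the choice is recorded here and in output metadata.
Regional comparisons use two-sided rank-sum tests, Bonferroni over
region pairs; hemisphere contrasts within region are uncorrected.

# Onset latency

At 1000 frames/s, each 1-ms post-onset bin is tested against the
pooled 500-ms baseline (uncorrected, two-sided). The onset latency is
the start of the first run of ≥ 15 consecutive significant bins; the
sustained-significance requirement is the multiplicity control, so no
per-bin correction is applied. The electrode latency is the minimum
over sentences with a detected onset. With a realistic onset ramp the
detector trails the true onset by a few milliseconds and almost never
leads it; on pure noise the 15-bin rule suppresses detections almost
entirely (both properties are measured in the test suite).

Latency distributions are compared between groups by two-sample
Kolmogorov–Smirnov tests on the latencies at or below each temporal
cutoff, for cutoffs 80–720 ms in 40-ms steps (the endpoints are the
analysis convention; the step is a package choice), Bonferroni
corrected over cutoffs × group pairs.

# Spatial clustering

Electrode coordinates are projected to the left hemisphere by negating
right-hemisphere x (idempotently), then clustered with full-covariance
Gaussian mixtures for k = 1…8. Clustering is done in 3-D; surface
flattening is out of scope. The number of clusters is selected by BIC;
the mean silhouette width (undefined at k = 1) is reported alongside,
with an agreement flag when both criteria coincide. Fits use
deterministic model-based hierarchical initialization; degenerate
covariances trigger a refit under a regularizing conjugate prior, and
a k that still fails is dropped with a warning.

# Encoding models by normalized reverse correlation

The lagged design matrix stacks the stimulus at delays 0–400 ms in
10-ms steps (a window that covers typical auditory STRF extents;
the same window is used for the semantic model so the two model
classes are comparable). NRC solves the normal equations on the
*centered* estimation data — weights are the pseudo-inverse of the
stimulus autocovariance applied to the stimulus–response
cross-covariance — with the autocovariance eigen-spectrum truncated at
eigenvalues below `tolerance × max(eigenvalue)`. Centering removes the
stimulus DC/"stimulus-on" mode, which would otherwise set the
truncation scale; an intercept absorbs the means. As the tolerance
shrinks the retained rank and the weight norm grow, and at vanishing
tolerance on full-rank problems the solution equals ordinary least
squares (a test asserts 1e-6 relative agreement).

The tolerance is chosen from the grid {0.5, 0.1, 0.05, 0.01, 0.005,
0.001} (a conventional reverse-correlation grid) to maximize the mean
cross-validated prediction correlation over 5 *contiguous-block* folds
within the estimation set — temporal autocorrelation makes shuffled
folds leaky. The held-out test set is a contiguous, seeded 10% block
cut at sentence boundaries and touches nothing in estimation (a
poisoned-test-set test asserts this by construction). Multi-electrode
fits share all design-side computation (fold cross-products and
eigendecompositions), which makes population fits cheap.

The semantic model maps every 10-ms frame inside a word to that word's
embedding vector (zero vectors outside words) and is fit by the same
NRC machinery on the same split. Model classes are compared per
latency group (cutoff 200 ms) by two-sided rank-sum tests on the
held-out correlations, reporting the winning direction.

The cochlear front-end for real audio is a gammatone filterbank
(50-ms FIR kernels, ERB bandwidths, unit-energy normalization) with
half-wave rectification, 30-Hz low-pass envelope extraction, cube-root
compression and 100-Hz framing — a documented substitute for the
original cochlear model, whose parameters are not reproduced here; all
synthetic-data analyses use the package's own front-end end to end.

# Modulation-domain tuning

The MTF is the magnitude of the unnormalized 2-D DFT of the STRF
weight matrix, so $\sum \mathrm{MTF}^2 = n_d n_b \sum w^2$ (Parseval,
asserted to 1e-10 against a direct double-sum DFT). Axes follow from
the sampling: temporal modulation in Hz from the 10-ms lag spacing
(signed, distinguishing upward from downward sweeps), spectral
modulation in cycles/octave from the band spacing, folded to
non-negative densities (the discarded half-plane is redundant by
conjugate symmetry). Marginals sum magnitude over the orthogonal axis
at each |rate| and are unit-L2-normalized.

Scalar tuning descriptors use L2 norms across the orthogonal axis
(spectral tuning per band, temporal tuning per delay). Best frequency
is the band-axis argmax of the spectral tuning vector restricted to
bands where the excitatory (positive) part dominates, ties resolving
to the lower band; purely inhibitory STRFs are flagged and fall back
to |weights|. These definitions are package conventions, recorded in
output metadata.

Group tuning is compared with a cosine-similarity permutation test on
the group-mean vectors: 1000 random relabelings, one-sided toward low
similarity, add-one p-value — calibrated size and high power against
orthogonal planted tuning are both measured in the test suite. Best
frequencies across regions use Kruskal–Wallis.

# Numerical and design notes

- **Determinism.** Every generator and every stochastic stage draws a
  child seed from the master seed via a tagged hash (`child_seed()`),
  so outputs are bit-identical across runs; the pipeline writes
  byte-identical CSV/JSON on reruns, and stage caches are keyed by a
  canonical config hash.
- **Rank-sum at scale.** The per-bin tests share one pooled baseline,
  so the implementation sorts the pool once and ranks each bin by
  binary search, falling back to exact tie handling only when ties are
  present; it matches `wilcox.test(exact = FALSE, correct = FALSE)`
  to machine precision.
- **Degenerate inputs.** Zero-variance electrodes, constant responses,
  zero-norm tuning vectors, all-zero STRFs and empty latency groups
  are rejected or returned as absent-with-reason rather than silently
  propagated.
- **Problem sizes.** The test-suite and acceptance experiments run at
  desk scale, chosen once: 60-s stimuli with 32 bands for encoding
  experiments (the full 64-band axis remains the generator default;
  recovery and ceiling properties do not depend on band count),
  16-dimensional embeddings for model-class discrimination, 100
  simulations for detector calibration, 500 null electrodes for
  family-wise error, 500 replicates for permutation-test size. The
  bundled demo (`demo_config()`) uses 4 sentences × 10 repeats with
  24 bands so the full pipeline completes in about a minute.
- **Onset-ramp calibration.** Detector calibration uses a 20-ms linear
  rise to a sustained plateau at 10 dB trial SNR — an onset shape in
  the range reported for high-gamma responses; an instantaneous step
  makes the detector exact to the bin, and slower ramps trade
  detection lag for the same ordering of results.

# Known limitations

- The generator's linear-drive-plus-Gaussian-noise model omits
  response nonlinearities, adaptation, cross-electrode correlated
  noise and trial-to-trial gain variability; calibration results are
  statements about the procedure, not about cortex.
- The semantic stand-in embeddings carry no lexical similarity
  structure, so semantic-model fits on synthetic data measure only the
  machinery, not semantic encoding per se.
- Tractography, functional connectivity, cortical-surface rendering
  and phoneme-level encoding models are out of scope.
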