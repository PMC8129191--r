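---
title: "Decoding self-related stimuli from SEEG band power: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding self-related stimuli from SEEG band power: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seegdecode)
```

# The problem

Stereo-electroencephalography (SEEG) records local field potentials from
depth-electrode shafts, each carrying 8–16 contacts, sampling distributed
cortical and subcortical sites at millisecond resolution. In the paradigm
this package targets, a subject hears or reads two stimuli — their own name
and a stranger's name — in a balanced pseudo-random sequence, and the
question is whether, where and when the neural response distinguishes the
two. The package turns a continuous multichannel recording with event
markers into: a single-trial decoding accuracy with a permutation
significance threshold, per-region contribution and single-region
accuracies, cross-modal region reports, response latencies, and a
three-class (rest / own / other) control analysis. A synthetic-SEEG
generator with known ground truth makes every stage testable without
patient data.

# The pipeline

The stages run in a fixed order, recorded in each result's provenance log.

**Line-noise contact screen.** Each contact's 50 Hz power is the mean
periodogram power within ±1 Hz of the line frequency. A contact is excluded
when its line power strictly exceeds the median across contacts plus 10
times their (unscaled) median absolute deviation. The strictness matters
for the degenerate case: with identical line power everywhere the MAD is
zero and nothing is removed.

**Comb notch.** Cascaded 4th-order Butterworth band-stops (±2 Hz) at 50,
100, 150, … Hz up to Nyquist. The cascade is applied through its
squared-magnitude frequency response on the full-length FFT — the exact
zero-phase equivalent of forward–backward filtering, without edge
transients, and one FFT per contact instead of one filter pass per
harmonic.

**Shaft-Laplacian reference.** Every kept contact is re-referenced against
the mean of its nearest kept neighbours along the same shaft; end contacts
use their single inner neighbour, and a contact left without neighbours is
excluded (`no_neighbor`). All referenced traces are computed from the
original signals simultaneously, so the operation is order-independent.
A spatially uniform signal maps exactly to zero on interior contacts.

**Band power.** A 6th-order Butterworth band-pass (high-gamma 60–145 Hz,
beta 13–30 Hz, or alpha 8–12 Hz), again applied as its zero-phase
squared-magnitude response, followed by the squared magnitude of the
analytic signal: `power(t) = |analytic(x)(t)|²`. For a unit in-band
sinusoid this gives power 1 away from the record edges, which the tests
assert to ±0.02.

**Epoching and baseline z-scoring.** Power is cut into 0–1,000 ms
post-onset windows and z-scored per trial and contact against the mean and
SD of that trial's own 200 ms pre-onset baseline. The raw (unnormalized)
post-onset and baseline power are retained because the latency tests need
them. A constant baseline (SD 0) is an error naming the trial and contact.

**Smoothing.** Convolution with a unit-area Gaussian kernel of 80 ms total
support. The kernel's σ is 80/6 ms — i.e. the stated window is read as the
±3σ support, the common convention when only a window length is given.
Boundary handling is reflective, so constants are preserved to 1e-9 and
linear ramps are exact in the interior.

**Artifact-contact rejection.** For each contact the across-trial mean
`M(t)` and standard error `SE(t)` of the smoothed z-power are compared; a
contact is removed when `SE(t) > |M(t)|` at any time point where `|M(t)|`
exceeds a floor. The comparison needs a floor because under the null
`M(t)` is itself of order `SE(t)`: near zero crossings `SE > |M|` holds by
chance alone, and with a floor below the null SE (~0.09–0.15 z at 60–120
trials) essentially every contact would be removed. The default floor is
0.25 z, about twice the null SE at these trial counts, which keeps clean
contacts while still catching a single wild trial (which shifts `M` by its
amplitude divided by the trial count and inflates `SE` to just above
`|M|`). Both the floor and an alternative reading of the rule
(`SE(t)` exceeding twice its own time average) are configuration options.

# Feature extraction and selection

Each contact's 1,000 ms z-power trace is averaged in 100 non-overlapping
10 ms bins (`v`); concatenating all kept contacts, contact-major, gives the
trial's feature vector `V`. For each feature, its per-trial values are
correlated with the binary class labels (Spearman r); the labels are then
shuffled 1,000 times, a Gaussian is fitted to the surrogate r-values, and
the p-value is the two-sided tail probability of the observed r under that
fit. The Gaussian fit is what resolves p-values far below the 1/1,000
Monte-Carlo floor, which matters because the significance threshold is
Bonferroni-corrected to 0.05 divided by the dimension of `V` (often below
1e-4). The 20 features with the smallest p-values form `V20`; ties are
broken by larger |r|, then provenance order. All 20 are always returned
and the number clearing Bonferroni is reported separately.

Selection is re-run inside every leave-one-out training fold by default,
so the held-out trial never influences which features are used to predict
it. A one-shot whole-session selection exists for reporting — which
regions and contacts contribute — and is never used for the headline
accuracy in per-fold mode.

Two implementation notes. First, for tie-free (continuous) features the
permutation null of the Spearman r against shuffled binary labels does not
depend on the feature: the feature's ranks are a permutation of 1..n, so
correlating them with a shuffled label vector has the same distribution
for every feature. The per-fold fast path exploits this with one shared
surrogate set per fold; the exported `spearman_perm_pvalue()` computes
per-feature surrogates, and a test confirms the two paths select the same
features. Second, fold ranks follow from full-data ranks by a one-element
update (dropping a trial shifts every larger rank down by one), so per-fold
selection costs one matrix crossproduct per fold.

# Classification and significance

The LDA path projects the selected features onto the principal components
explaining >90% of training-fold variance (typically 2–6 with correlated
neural features) and fits a linear discriminant on the scores; the random
forest uses 200 trees with the √d per-split feature subsampling
convention. Validation is leave-one-out; PCA, selection and the classifier
are all fitted per fold.

Significance of an accuracy keeps the predicted labels fixed and re-scores
them against 1,000 label permutations (class counts preserved). The
threshold is the 95th percentile of that empirical distribution, taken as
the inverse-ECDF percentile so it sits on the discrete accuracy grid, and
the p-value is the fraction of permuted accuracies at least as large as
observed. For balanced predictions at n trials the permuted agreement
count is `2X` with `X` hypergeometric, which the tests use as an
independent oracle. At n = 120 the population 95th percentile falls on an
atom boundary (CDF 0.95002 at X = 34), so a single Monte-Carlo threshold
legitimately flips between 56.7% and 58.3%; comparisons against the oracle
therefore use the expected threshold over seeds.

**A calibration caveat worth knowing.** This permutation test conditions
on the prediction vector and models only re-pairing noise (sd ≈ 4.6
accuracy points at n = 120). Leave-one-out predictions, however, share
118 of 119 training trials: per-fold selection latches onto the same
spuriously correlated features in every fold, prediction errors become
correlated across folds, and the null sampling sd of the LOO accuracy is
roughly 11 points — individual predictions remain unbiased (a single-fold
check gives P(correct) ≈ 0.5), but the whole-session accuracy fluctuates
more than the permutation band allows. In our null calibration the
observed accuracy exceeds its own permutation threshold in roughly a fifth
of runs rather than 5%. This is a property of the validation scheme
itself, not of any implementation choice; the mean null accuracy is well
calibrated at 50%.

# Region, cross-modal and latency analyses

Selected-feature provenance is grouped by anatomical label (labels are
free strings, matched case-insensitively after whitespace normalization;
no atlas is mandated). The maximal contributor — ties flagged jointly — is
re-decoded alone: the full selection + LOO pipeline restricted to the
region's contacts. A region is cross-modal when its accuracy strictly
exceeds the significance threshold in both the auditory and the visual
session; by default every single region is held to the multi-region
threshold of its modality, which makes regions comparable within a
subject. Cross-modal contacts are those contributing selected features to
the region in both modalities; proportions are pooled counts over the
pooled total.

Stimulus similarity is the normalized zero-lag (auditory, Hilbert
amplitude envelopes) or zero-shift (visual, 2-D) cross-correlation,
computed as the Pearson correlation of the aligned samples: both inputs
are mean-centered and scaled by the geometric mean of their energies, so
self-similarity is exactly 1, a mean-centered negation gives −1, and
independent stimuli give ≈0. An ordinary least-squares regression of
single-region accuracy on similarity asks whether decoding merely reflects
the stimuli's physical difference.

Response latency is the start of the first 10 ms bin whose amplitude
differs significantly from baseline (activation latency: per-trial
baseline means vs per-trial bin means, two-sample permutation test) or
between classes (difference latency), at α = 0.05 per bin, uncorrected.
Two numerical choices protect the first-crossing estimator. First, bin
amplitudes for the latency tests are computed from the *unsmoothed* power
(normalized against each trial's own baseline), because the 80 ms
smoothing spreads response energy backwards and biases first crossings
40–60 ms early. Second, with 100 uncorrected bins a single significant
bin occurs somewhere in ~99% of null traces, so the pipeline requires a
run of consecutive significant bins — 3 by default in `analysis_config()`,
which brings the family-wise false-onset rate to ~1% while a sustained
response still reports the first bin of its run. The exported latency
functions default to the plain single-bin crossing (persistence 1) so the
raw behaviour remains available. Feature generation times are summarized
by a Gaussian KDE (Silverman bandwidth) truncated to the stimulus window
and renormalized; with fewer than 5 times a histogram fallback is flagged.

# The three-class control

The 1,000 ms interval preceding every second stimulus onset provides a
rest class of the same size as each name class; taking every second event
keeps the design balanced, which keeps chance at 33% and the LDA priors
neutral. Rest windows are z-scored against their own first 200 ms,
symmetric with stimulus epochs. Selection runs pairwise — (rest, own),
(rest, other), (own, other) — keeping 10 features per pair with Bonferroni
correction within each execution, for 30 feature slots in total
(duplicates retained as distinct slots). Performance is reported per class
as sensitivity `TP/(TP+FN)` and precision `TP/(TP+FP)` (both ×100), the
3×3 confusion matrix, and one-vs-rest ROC/AUC from the classifier scores
(LDA posteriors or forest vote fractions).

# The synthetic generator

`generate_session()` builds continuous signals as 1/f^a background noise
(default exponent 1, amplitude 20 µV — the periodogram-slope test holds
the exponent to ±0.3), optional 50 Hz line contamination, and, per
`effect_spec()`, a band-limited noise component gated on during the
specified window of matching-class trials. The component's RMS is
`sqrt(gain² − 1)` times the background's RMS inside the band, so total
band RMS during the response is exactly `gain` times baseline, and
`gain = 1` adds nothing — the null is exact, and label exchangeability
under the null is tested directly. Gating uses 20 ms raised-cosine ramps
placed *inside* the response window, so no effect energy precedes the
nominal onset that the latency suite tries to recover. Events follow the
protocol defaults: 1,000 ms stimuli, 1,000 ms inter-trial interval,
optional uniform jitter (e.g. 100–300 ms), 120 trials split evenly over
the classes in a pseudo-random balanced sequence. Recordings are padded to
5-smooth lengths so every spectral step uses fast FFT sizes.

The default montage is 2 shafts × 8 contacts. Clinical implants carry
100–150 contacts; the smaller montage changes compute cost, not the
statistical structure of any stage, and the acceptance analyses state
their sizes explicitly (16 contacts and 120 trials for null calibration
and recovery; 8 contacts with 60 trials for the effect-size ladder and the
three-class control; 10–20 seeds per summary). What the generator does not
emulate: volume conduction and realistic spatial covariance beyond the
shaft-Laplacian neighbourhood, non-stationary artifacts, behaviour-locked
latency jitter, and real speech or text stimuli. Passing tests therefore
demonstrate that the implementation recovers the structure it models — not
that the method's assumptions hold in any particular patient recording.

Stimulus pairs for the similarity oracle are amplitude-modulated tones
whose envelopes are mixed after exact Gram–Schmidt orthogonalization (the
sample correlation equals the requested similarity) and binary raster
images where pixels flip with probability `(1 − similarity)/2`.

# Defaults and knobs

| parameter | default | meaning |
|---|---|---|
| band | high_gamma (60–145 Hz) | analysis band; beta/alpha available |
| baseline_ms | 200 | per-trial baseline for z-scoring |
| window_ms | 1000 | post-onset analysis window |
| smooth_ms | 80 | Gaussian kernel support (σ = 80/6 ms) |
| bin_ms | 10 | feature bin length (100 bins) |
| k / k_per_pair | 20 / 10 | selected features (two-/three-class) |
| n_perm_* | 1000 | permutations (selection, accuracy, latency) |
| mad_mult | 10 | line-noise screen threshold multiplier |
| artifact_floor | 0.25 z | minimal \|M(t)\| for the artifact rule |
| latency_persistence | 3 | consecutive significant bins for a latency |
| selection_mode | per_fold | anti-leakage selection scoping |

# Known limitations

The accuracy-permutation threshold under-covers the sampling variance of
leave-one-out accuracies (see the calibration caveat above). The
single-bin latency estimator is deliberately available but fragile; the
persistence criterion is the recommended setting. EDF import is lossy by
format (16-bit quantization of the channel range); the HDF5 container is
the lossless native format. The two-way ANOVA band/classifier summary
assumes a balanced table and is a convenience report, not part of the
decoding pipeline.
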