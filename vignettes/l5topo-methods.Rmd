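---
title: "Methods: tonotopy and ensemble analysis of layer-5 auditory cortex imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tonotopy and ensemble analysis of layer-5 auditory cortex imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l5topo)
```

`l5topo` implements the downstream analysis of calcium-imaging recordings
from layer 5 of mouse auditory cortex, where corticocollicular (CC) neurons —
the layer-5 cells projecting to the inferior colliculus — can be recorded
alongside other pyramidal (non-CC) neurons. The package covers two recording
modalities and four analysis layers:

1. **Widefield mapping** — per-pixel best-frequency (BF) maps from
   low-magnification fluorescence movies, with tonotopic reversal-point and
   cortex-boundary detection used to scaffold subfield parcellation
   (A1 / AAF / A2).
2. **Single-cell screening and tuning** — responsiveness tests and gaussian
   frequency-tuning classification of deconvolved two-photon traces.
3. **Local topography** — the interquartile range (IQR) of tuning values in
   a 100-µm neighbourhood as a measure of local tonotopic heterogeneity.
4. **Ensemble analysis** — correlation-based clustering of population
   responses to pure tones and animal vocalizations, with a label-shuffle
   null to discard clusters at noise level.

Raw imaging data of this kind is not publicly deposited, so the package ships
first-class synthetic-data generators with planted ground truth; every
analysis stage is validated by recovering what was planted.

## Stimulus protocols

Tone grids are geometric. The two-photon grid spans 4-64 kHz in 4 steps per
octave (17 tones) crossed with 5 sound levels (30-70 dB SPL in 10-dB steps),
10 repetitions per combination (85 combinations, 850 presentations); tones
last 250 ms, followed by a 1-s pause, at ~30 frames/s. Each sound level is
acquired as a separate recording. The widefield protocol uses 5 tones
(octave steps) at 70 dB, 500 ms + 5-s pause, 16 repetitions, at 10 Hz.
Vocalization sessions present 10 animal sounds 10 times each; because the
sounds differ in duration, all analyses use the first 550 ms of each sound.

All frequencies are carried internally on the octave axis
$x = \log_2(f / 4\,\mathrm{kHz}) \in [0, 4]$; bandwidths and IQRs are in
octaves. Presentation order is re-randomized per repetition block (the
protocol source states randomization without fixing a block structure;
block-wise permutation guarantees every stimulus appears exactly once per
block). Every source of randomness takes an explicit seed; there is no
hidden global state.

## Widefield pipeline

Movies are block-averaged to the analysis resolution (256×256 for the real
acquisition geometry). The temporal baseline $F_0$ of each pixel is a
degree-3 polynomial fitted over a 15-s window centred on each frame —
equivalent to Savitzky–Golay smoothing — with the window truncated (not
padded) at the recording edges; the signal is expressed as
$\Delta F/F_0 \cdot 100$. Pixels whose baseline ever reaches zero or below
are excluded.

For each presentation, the baseline distribution is taken from the 2-s
prestimulus period (used through its mean and SD; no histogram binning is
needed), and the response is the maximum of the 750-ms post-onset window
averaged with its preceding and following frame. Responses with z > 2 are
tone-evoked. A frequency-specific amplitude is the mean of evoked amplitudes
and requires evoked responses in at least 2/16 repetitions (sparse
CC-limited labelling) or 4/16 (general labelling). The pixel's BF is the
frequency with the highest amplitude; ties break toward the lower frequency
(deterministic). Overlapping fields of view are stitched after dividing each
FOV's amplitudes by the FOV maximum; the map with the higher normalized
amplitude wins at shared pixels.

Reversal points: from each low-frequency hub centre (automatic mode: the
centroid of the largest connected component of lowest-BF pixels; the original
analysis identified hubs by eye), 1,440 radial vectors (0.25° steps) are
scanned. BF values of responsive pixels within ±1° are averaged per 1-pixel
radial bin; within ~30 px of the centre the ±1° wedge is thinner than a
pixel, so empty bins fall back to nearest-pixel sampling along the exact
ray. Profiles are smoothed with a 10-sample moving average and a gaussian
filter, and the first local maximum marks the reversal. The phrase
"gaussian filter (degree 3)" in the source method is ambiguous between a
smoothing kernel and a mixture fit; it is implemented here as gaussian
smoothing with σ = 3 samples, which we do not claim as the original authors'
intent. The cortex boundary along each ray is the first run of 10
consecutive unresponsive pixels, placed at the run start.

## Responsiveness screening

For every neuron and frequency-SPL combination, mean spike probabilities are
computed over 400-ms windows ending at (pre) and starting at (post) the
onset frame — `floor(0.4 × frame rate)` frames, 12 at 30 fps. A one-way
ANOVA compares the 10 pre-repetition means against the 10 post means; with
two groups this F-test equals the squared pooled-variance t statistic (a
test asserts the identity against `stats::aov`). A neuron is non-responsive
if p > 0.01 in *every* combination; p ≤ 0.01 counts as significant, matching
the screening rule verbatim. For downstream BF analysis a combination is
`significant` only when post > pre (the ANOVA is two-sided but BF is defined
on excitatory responses); the signed rule can be disabled
(`signed_bf = FALSE`). Zero variance in both groups with equal means yields
p = 1 by convention. The per-repetition means (10 vs 10) are used rather
than per-frame values, as the natural reading of windowed-mean screening.

## Tuning classification

The frequency response area (FRA) is the 17×5 matrix of mean post-onset
responses. It is collapsed to a 17-point curve by averaging across SPLs, and
two models are fitted on the octave axis by bounded Levenberg-Marquardt
(`minpack.lm::nlsLM`, multi-start):

$$\mathrm{gauss1}(x) = A_1 e^{-\left(\frac{x-B_1}{C_1}\right)^2} + D$$
$$\mathrm{gauss2}(x) = A_1 e^{-\left(\frac{x-B_1}{C_1}\right)^2} +
  A_2 e^{-\left(\frac{x-B_2}{C_2}\right)^2} + D$$

Bounds: $A \ge 0$, $B \in [-1, 5]$, $C \in (0.05, 8]$, $D$ free; starts
place $B$ at the curve maximum (and the second-highest local maximum for the
bimodal model) with $C \in \{0.25, 0.5, 1\}$ and $D = \min y$. Bimodal peaks
are reported in canonical order $B_1 < B_2$. Model choice uses the adjusted
coefficient of determination, $R^2_{adj} = 1 - (1 - R^2)(n-1)/(n-p-1)$ with
$n = 17$ and $p = 4$ or $7$: both fits below 0.3 classify the neuron as
*irregular*; otherwise the better fit decides *single* vs *double*.

Two identifiability safeguards apply before the bimodal model may win.
Under bounded least squares a fitted amplitude is never exactly zero, so a
positivity check alone is vacuous: a "second peak" with 2% of the main
amplitude, or narrower than the stimulus grid, is a noise wiggle, not a
peak. The bimodal fit is therefore eligible only if (a) the smaller
amplitude is at least 10% of the larger, (b) the peaks are at least one grid
step apart, and (c) each peak's full width at half maximum lies between one
grid step and the span of the frequency axis. These constants derive from
the grid geometry (0.25 and 4 octaves for the standard grid), not from data.

Bandwidth is the FWHM of a fitted peak. For $e^{-((x-B)/C)^2}$ this is
$\mathrm{BW} = 2C\sqrt{\ln 2}$ octaves (the printed source formula is
typographically garbled; this closed form is verified against numeric
half-maximum root finding to 1e-9). Best frequency (BF) is the tone with the
strongest *significant* response at any SPL (ties toward the lower
frequency); center frequency (CeF) is $B_1$ of the unimodal fit, computed
for all responsive neurons regardless of class. Whether a double-peaked
neuron contributes one or two bandwidths to pooled statistics is left to the
caller; both peak bandwidths are reported.

## Local heterogeneity

For each neuron, the BFs (or CeFs) of all same-population neurons within a
100-µm radius (centre included, 2-D distance in the imaging plane) are
collected; with at least 5 neighbours the IQR (linear-interpolation
quartiles, `quantile` type 7 — pinned by an exact brute-force oracle test)
measures local heterogeneity in octaves. A subsampling control randomly
excludes 50-80% of neurons per subfield before the calculation, to rule out
sample-size artifacts when populations of different size are compared.

## Ensemble analysis

Per neuron and repetition, windowed mean responses to all stimuli (400 ms
for pure tones at 50 dB, matching the tuning window; 550 ms for
vocalizations) are concatenated into a *sound vector*. Vectors are Pearson-
correlated across repetitions: within a neuron, the mean over distinct
repetition pairs is its *reliability*; between neurons, the mean over
repetition pairs excluding equal trial indices (a ≠ b) is their response
similarity — excluding a = b keeps shared single-trial noise out of the
estimate (`pair_mode = "all"` exposes the alternative). Zero-variance
vectors make a neuron's correlations undefined; it is excluded from
clustering but kept in the FOV denominator for the clustered fraction.

Neurons are clustered per FOV on the dissimilarity 1 − correlation with
average-linkage hierarchical trees cut by a dynamic hybrid tree cut
(`deep_split = 0.5`, minimum cluster size 3 — ensemble data show mean
cluster sizes near 4, far below the size-20 default of gene-network
applications; linkage and minimum size are configurable). The cut identifies
branches that are large enough, internally tight (mean pairwise core
dissimilarity below a scatter threshold) and separated (attachment height
minus the branch's mean internal merge height above a gap threshold), then
assigns leftover objects to the nearest cluster by average dissimilarity.
The scatter/gap thresholds interpolate the standard deep-split tables, and
the fractional setting 0.5 is interpolated linearly. The branch height uses
the *mean* internal merge height: the last merge alone reflects only the
straggliest member and understates the separation of an otherwise tight
branch. The reference implementation of the hybrid cut is not redistributed
with this package; the implementation is validated behaviourally (planted
block structure, determinism, object-order invariance, degenerate inputs).

The shuffle null re-assigns each neuron's windowed responses to stimulus
identities at random, independently per neuron and repetition (this
granularity destroys both tuning and reliability, matching the null's
purpose), re-clusters, and pools the mean correlations of all shuffled
clusters over 5 passes. A real cluster is retained only if its mean
within-cluster correlation exceeds the null mean by more than 2 null SDs.
Note that under a pure-noise input this mean + 2 SD rule has an intrinsic
false-retention rate near 5% at typical cluster counts; the package reports
it honestly rather than recalibrating the published rule. Cluster statistics
follow the reporting conventions of ensemble studies: clusters and clustered
fraction per FOV; size, mean correlation and mean reliability per cluster;
Euclidean distance in µm per within-cluster neuron pair.

## Group comparisons

Two-sample summaries route by a Kolmogorov-Smirnov normality test against a
gaussian with sample-estimated mean and SD (a Lilliefors-style usage whose
conservativeness is accepted and documented; routing level 0.05, not stated
by the source). Normal pairs use the unpaired two-tailed pooled-variance
t-test, others the Mann-Whitney U test; Bonferroni correction multiplies by
the number of comparisons. Simulations in the test suite bound the routed
procedure's type-I error at ≤ 0.06 for nominal 0.05.

## Synthetic data: what it emulates and what it does not

`simulate_two_photon` plants, per neuron: a position in a 500-µm FOV, a
neuron type (CC / non-CC), a tuning class (defaults 60% single / 6% double /
34% irregular, near reported awake fractions), a BF on the tone grid from an
affine tonotopic gradient (4 octaves across the FOV) with gaussian scatter
(σ = 0.5 octave by default), and a bandwidth (FWHM ~ N(0.4, 0.08) octaves,
matching awake CC-scale values). A trial response is the planted tuning
curve times a saturating SPL gain (no SPL response model is given by the
source; monotone saturation is the package's choice), a Bernoulli
reliability draw, and lognormal amplitude jitter with trial CV 0.3, embedded
as a *single-frame impulse* at the onset frame — deconvolved traces are
impulse-like, and the windowed mean then equals magnitude / window-frames.
Irregular neurons draw i.i.d. mean responses per combination. Noise is
additive gaussian clipped at zero (traces are non-negative).

`simulate_vocal_responses` gives each motif a template over the 10 sounds
(Uniform(4, 9) response units); members receive the template plus
independent noise with SD $\sigma_s\sqrt{(1-\rho)/\rho}$ so the expected
within-motif vector correlation equals ρ. The template floor keeps clipping
at zero negligible, preserving that calibration. Neurons outside any motif
respond with stimulus-independent draws — no reliability, no between-neuron
correlation — so a fully unstructured population is genuinely at noise
level. Motif members scatter around their centre with a configurable spatial
SD.

`simulate_widefield` plants a radial map: a low-frequency hub, BF rising
linearly to the highest tone at the reversal radius and falling beyond it,
an unresponsive band marking the cortex end, a drifting baseline, a
double-exponential calcium kernel (1-s decay — unspecified by the source;
it only needs to be slow relative to 10-Hz frames — peak normalized to 1 so
the planted amplitude is in ΔF/F percent), and clipped gaussian noise.

What the generators do **not** emulate: raw (un-deconvolved) fluorescence,
neuropil contamination, motion artifacts, segmentation errors, correlated
(shared) noise across neurons, SPL-dependent tuning-width changes, and
realistic vocalization spectrotemporal structure. Passing recovery tests
therefore demonstrates correctness of the analysis given idealized inputs
of the assumed statistical structure, not robustness to acquisition
artifacts handled upstream (registration, segmentation, deconvolution).

## Problem sizes and numerical choices

Validation runs use desk-scale sizes chosen as the package's own test
conditions: 500 neurons for tuning recovery, 120 neurons (10,200 null
combinations) for the type-I check, 20 seeds × 200 neurons per scatter level
for heterogeneity, 20 seeds of 3 × 15-neuron motif populations for
clustering, and 64×64-pixel widefield grids over the full 80-presentation
schedule (the generator's default geometry remains 256×256 at 10 Hz). The
end-to-end demo pipeline (`run_pipeline`) runs 120 neurons and completes in
well under a minute; rerunning with the same seeds is byte-identical, with
CSV output fixed at 6 significant digits for diff-stability.

Degenerate inputs are handled explicitly: constant traces give p = 1 and are
non-responsive; constant tuning curves route to the irregular path; zero
baseline SD marks a presentation non-evoked; all-identical dissimilarities
yield a single cluster or none, never a crash; an empty shuffle null retains
all clusters with a warning.

## Known limitations

* The manual subfield border drawing and the multi-animal template
  ("master map") alignment of the original workflow are interactive and
  data-dependent; the package provides their quantitative scaffolding
  (BF maps, reversal points, boundary points) only.
* The hybrid tree cut is a faithful but independent implementation; exact
  assignment-level agreement with the original reference implementation is
  not asserted.
* Pre-registered inputs are assumed: ROI positions arrive in a common
  µm frame, and neuron-type labels are taken as given.
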