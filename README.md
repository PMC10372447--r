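# l5topo

Tonotopy and ensemble analysis of layer-5 auditory-cortex calcium imaging.

Layer-5 corticocollicular (CC) neurons — the pyramidal cells of auditory
cortex that project to the inferior colliculus — sit deep in cortex, and how
their sound responses are organized in space, and how they act as population
ensembles, differs from other layer-5 neurons. Answering those questions from
imaging data requires a chain of analyses: mapping best frequency (BF) across
the cortical surface from widefield movies, screening single two-photon
neurons for responsiveness, classifying their frequency tuning, quantifying
how orderly the local tonotopic map is, and finding correlated activity
ensembles with a proper noise control. `l5topo` implements that chain as a
tested, reusable R package, together with synthetic-data generators that
plant known ground truth so every stage can be validated by recovery.

## What it computes

* **Widefield BF maps**: per-pixel ΔF/F against a 15-s degree-3 polynomial
  baseline; a response is tone-evoked when the 750-ms post-onset peak
  (averaged with its neighbouring frames) exceeds the 2-s prestimulus
  distribution by 2 SD; frequencies qualify with ≥ 2/16 or ≥ 4/16 evoked
  repetitions; BF is the frequency with the highest mean evoked amplitude.
  Maps are stitched across fields of view, scanned by 1,440 radial vectors
  (0.25° steps) for tonotopic reversal points, and bounded by the first run
  of 10 unresponsive pixels (the end of auditory cortex).
* **Responsiveness**: per frequency-SPL combination, a one-way ANOVA on the
  400-ms pre- vs post-onset window means (10 repetitions each); a neuron
  with p > 0.01 in all 85 combinations is non-responsive.
* **Tuning**: the frequency response area is collapsed across SPLs and
  fitted with unimodal and bimodal gaussians on the octave axis
  (`A·exp(−((x−B)/C)²) + D`); adjusted R² with a 0.3 cutoff classifies
  neurons as single-peaked, double-peaked or irregular. Bandwidth is the
  full width at half maximum, `BW = 2·C·√(ln 2)` octaves; BF is the tone
  with the strongest significant response; center frequency (CeF) is the
  unimodal fit peak.
* **Local heterogeneity**: the interquartile range of BF (or CeF) among all
  neurons within 100 µm (≥ 5 neighbours), in octaves — high IQR means weak
  local tonotopy — plus a random-subsampling control.
* **Ensembles**: per-repetition "sound vectors" of windowed responses
  (400 ms for pure tones at 50 dB, 550 ms for vocalizations), Pearson
  correlations across repetitions (reliability within neuron, similarity
  between neurons), average-linkage clustering cut by a dynamic hybrid tree
  cut (deepSplit 0.5, minimum size 3), and a 5-pass stimulus-shuffle null:
  clusters are kept only if their mean correlation exceeds the shuffled
  clusters' mean by 2 SD. Cluster count, size, clustered fraction, pairwise
  distance, correlation and reliability are reported.
* **Group comparisons**: Kolmogorov-Smirnov normality routing to unpaired
  two-tailed t-tests or Mann-Whitney U tests, with Bonferroni correction.

## Worked example

Simulate an awake-style two-photon session (17 tones × 5 SPLs × 10
repetitions, 150 neurons with planted tuning), run the screening and tuning
chain, and measure local heterogeneity:

```r
library(l5topo)

proto <- make_protocol("two_photon_pt", seed = 1)
proto
#> <stim_protocol> two_photon_pt
#>   tones: 17 (4.0-64.0 kHz)
#>   SPLs: 30, 40, 50, 60, 70 dB; 10 repetitions; 850 onsets; 30 fps; 32625 frames

sim    <- simulate_two_photon(proto, pt_population_config(n_neurons = 150), seed = 8)
tuning <- tune_neurons(sim$traces)
table(tuning$tuning_class)
#>    double irregular    single
#>        10        47        93
```

The planted mixture was 60% single / 6% double / 34% irregular; the
classifier recovers 93 / 10 / 47 of 150. Single-peaked bandwidths centre on
the planted 0.4-octave FWHM:

```r
summary(tuning$bw_oct[tuning$tuning_class == "single"])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.1536  0.3149  0.4005  0.3930  0.4639  0.9935

iq <- local_iqr(data.frame(x_um = sim$traces$rois$x_um,
                           y_um = sim$traces$rois$y_um,
                           value = tuning$bf_oct))
mean(iq$iqr_oct, na.rm = TRUE)
#> [1] 1.06
```

The mean local IQR of 1.06 octaves reflects the planted 0.5-octave scatter
plus the gradient's own change across each 100-µm neighbourhood. Ensemble
analysis of a vocalization session with three planted 15-neuron motifs at
within-motif correlation 0.4:

```r
voc  <- make_protocol("two_photon_voc", seed = 2)
simv <- simulate_vocal_responses(voc, motif_config(), seed = 3)
ens  <- analyze_ensembles(simv$traces, "vocal", seed = 4)
ens$clusters$clusters
#>   cluster size mean_corr   status
#> 1       1   15 0.3926150 retained
#> 2       2   15 0.3820657 retained
#> 3       3   15 0.3782218 retained
mean(ens$stats$pair_distances_um)
#> [1] 236.3
```

All three motifs are recovered at their planted size and correlation level
and survive the shuffle-null filter; the mean within-cluster pair distance
reflects the planted 150-µm spatial dispersion. `run_pipeline()` executes
the full chain (protocols → synthesis → screening → tuning → heterogeneity →
ensembles → group comparison) and writes CSV outputs plus a JSON manifest;
reruns under the same seeds are byte-identical.

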