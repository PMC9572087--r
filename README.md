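# harfeatures

Feature extraction, ranking and evaluation for human activity
recognition (HAR) from tri-axial accelerometer recordings.

Recognising activities of daily living — walking, jogging, stair
climbing, sitting, standing — from a wrist- or waist-worn accelerometer
is a standard task in digital health, but there is little consensus on
*which* signal features carry the discriminative information.
`harfeatures` implements a complete feature-significance framework:

* **Windowing and gravity removal** — 2.5 s sliding windows, zero-phase
  Butterworth high-pass (0.5 Hz), magnitude channel
  `MG = sqrt(x² + y² + z²)`.
* **A 193-feature descriptor per window** over the signals x, y, z, MG,
  in five groups: time domain (mean, SD, RMS, autocorrelation, PCA
  loadings, Dxyz, signal magnitude area), frequency domain (spectral
  peaks, band powers, FFT magnitudes and entropy, total harmonic
  distortion), time–frequency (5-level wavelet packet decomposition),
  repeatability–regularity (recurrence quantification analysis RR /
  DET / ENTR / L, permutation entropy, largest Lyapunov exponent by the
  small-data-quantity method), and Burg AR(5) autoregression.
* **Feature ranking** by Joint Mutual Information Maximisation (JMIM):
  starting from the feature with maximal mutual information with the
  class `C`, greedily add
  `f = argmax_{f_i ∈ F−S} ( min_{f_s ∈ S} I(f_i, f_s; C) )`,
  computed from equal-width-discretised features.
* **Incremental evaluation** — stratified 5-fold cross-validation of
  the top-s features for growing s, with KNN (k = 3) and a linear SVM,
  reporting macro-averaged accuracy, precision, recall and F-measure,
  plus an ablation mode that quantifies the accuracy contribution of
  the regularity-sensitive ("uncommon") feature group.
* **A synthetic recording generator** (static, periodic and chaotic
  activity classes; surrogate-data regularity benchmarks) so the whole
  pipeline is testable and reproducible without any dataset download,
  and readers for common public-dataset text layouts (generic CSV,
  WISDM-style, PAMAP2-style).

## Worked example

```r
library(harfeatures)

# 4-class synthetic benchmark: sit, stand, walk (1.8 Hz), jog (2.8 Hz)
rec <- generate_recording(default_activity_specs(), fs = 50, seed = 1)
rec
#> <har_recording> 24000 samples @ 50 Hz (480.0 s)
#>   classes: jog (6000), sit (6000), stand (6000), walk (6000)

w  <- segment_recording(rec)              # 192 sequential 2.5 s windows
ft <- extract_features(w)                 # 192 x 193 feature matrix
nf <- normalize_features(ft)
rk <- jmim_select(discretise_ewd(nf, 10), attr(ft, "labels"))
head(as.data.frame(rk), 3)
#>   rank   feature_name    score
#> 1    1 peak5_height_y 1.268052
#> 2    2         acf2_y 1.386294
#> 3    3 peak5_height_x 1.369129

cv <- cross_validate(nf, rk, subset_sizes = c(1, 10, 30, 193),
                     folds = 5, seed = 1, labels = attr(ft, "labels"))
as.data.frame(cv)
#>   size classifier accuracy_macro accuracy_overall precision recall f_measure
#> 1    1        svm          0.979            0.958     0.959  0.958     0.958
#> 2    1        knn          0.977            0.953     0.953  0.953     0.953
#> 3   10        svm          1.000            1.000     1.000  1.000     1.000
#> 4   10        knn          1.000            1.000     1.000  1.000     1.000
#> 5   30        svm          1.000            1.000     1.000  1.000     1.000
#> 6   30        knn          0.997            0.995     0.995  0.995     0.995
#> 7  193        svm          1.000            1.000     1.000  1.000     1.000
#> 8  193        knn          0.995            0.990     0.990  0.990     0.990
```

Reading the output: the ranking lists features in selection order with
the JMIM goal-function value at each step (the first entry is the
single-feature mutual information with the class, in nats). The curve
shows that a single well-chosen feature already separates these four
synthetic classes almost perfectly, and ten suffice for both
classifiers — the synthetic classes are deliberately well separated;
see the vignette for what this does and does not imply about field
recordings. `run_pipeline()` wraps all of the above and writes
`features.csv`, `ranking.csv`, `curve.csv`, `report.json` (top features
with group tags and the ablation pair) and `manifest.json` to a
directory; `inst/cli/har_pipeline.R` exposes the same stages as
command-line verbs (`synth`, `extract`, `select`, `evaluate`, `run`).

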