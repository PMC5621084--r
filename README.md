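# PostureSense

Automatic classification of adequate vs. inadequate work postures from two
wearable sensors: a four-sensor instrumented insole and a helmet-mounted
accelerometer. The package targets occupational-health researchers and
engineers who need an inexpensive, non-vision-based way to flag posture
patterns associated with work-related musculoskeletal disorders.

Six work situations are distinguished — static load carriage, dynamic
handling, and static standing, each in an adequate and an inadequate
variant. The pipeline:

1. **Center of pressure.** From sensor pressures `P_i` at insole
   coordinates `(X_i, Y_i)`, the COP is the barycenter
   `X_COP = Σ X_i P_i / Σ P_i` (and likewise `Y_COP`), per sample.
2. **Direct features (60).** Statistics of the stabilograms, COP
   velocities, statokinesigram geometry (path length, amplitudes, the 90%
   prediction-ellipse area, length-over-surface ratio), spectral mean and
   median frequencies, and head-acceleration statistics.
3. **Graphic features.** The 43 × 134 mm insole area is discretized into a
   binary occupancy grid (e.g. 18 × 55 = 990 cells at ≈ 2.4 mm); each cell
   visited by the COP becomes a binary feature.
4. **Hybrid feature selection.** A filter stage (Fisher, two-sample t,
   Pearson, ANOVA, ReliefF; normalized and optionally aggregated) keeps the
   top 20 features; a sequential-forward-selection wrapper around the
   classifier orders them by cross-validated accuracy and keeps the
   shortest near-optimal prefix.
5. **Classification.** An i–12–6 tanh/softmax multilayer perceptron trained
   by conjugate gradients under the cross-entropy loss, evaluated with
   10 × 10-fold stratified cross-validation.

Because no participant recordings are distributed, the package ships a
seeded synthetic-trial generator (`generateCorpus()`) that reproduces the
statistical contrasts the features measure, so the entire pipeline is
testable and benchmarkable end to end.

## Worked example

```r
library(PostureSense)

layout <- defaultLayout()                       # 4 sensors, 43 x 134 mm
corpus <- generateCorpus(nPerSituation = 20, seed = 1)

direct <- extractDirect(corpus, layout)        # 120 trials x 60 features
dim(featureValues(direct))
#> [1] 120  60

sel <- hybridSelect(direct, variant = "ttest2", seed = 1, maxit = 100)
sel
#> SelectionResult: 20 candidates, 3 selected (best CV rate 1.000)
#>   selected: Ym, AccYrms, Yrms

report <- evaluateCv(direct, selectedFeatures(sel),
                     repetitions = 10, folds = 10, seed = 1, maxit = 100)
meanRate(report)
#> [1] 0.9983333
```

The selected subset mixes insole and helmet information — the mean
anteroposterior COP position (`Ym`), its RMS, and the RMS anteroposterior
head acceleration — and classifies the six situations with a mean
recognition rate of 99.8% under 10 × 10-fold CV on this synthetic corpus.
Adding the hybrid-selected resolution-990 graphic features
(`extractGraphic()`, `combineFeatures()`) gives a combined table whose
selected subset scores 97.1%; the graphic features alone reach 82.1%.

A thin command-line front end is provided in
`inst/scripts/posture-pipeline.R`:

```sh
Rscript inst/scripts/posture-pipeline.R full --seed 1 --out posture-out
```

which writes the four benchmark evaluation reports (filter-only, direct
hybrid, graphic hybrid, combined) plus the selection traces as CSV/JSON.

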