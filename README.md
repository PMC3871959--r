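# sigspace

Automated, parallel signal processing and supervised classification of
windowed multichannel time series — the kind of data produced by
event-related-potential (ERP) experiments in EEG, where a rare
task-relevant "Target" stimulus evokes a stereotyped deflection (P300)
that must be told apart from the response to frequent "Standard" stimuli.

The package is aimed at researchers who want to *benchmark* processing
choices rather than run one hand-written script: which spatial filter
(xDAWN, CSP, PCA, or none), how many retained pseudo-channels, which
classifier regularization — evaluated systematically over datasets,
parameter grids and seeded repetitions, with all results in one table.

## The model

Data flow through four sample granularities:

```
raw stream  --segment-->  time-series window  --features-->  feature vector
            (markers,      (T x C amplitude      (flattened,  --classify-->
             cutting        matrix)               normalized)  prediction
             rules)
```

Processing steps are **nodes** with a uniform contract (optional training
phase + an execute function); nodes concatenate into **node chains** from
a source to a sink. Trainable nodes (spatial filters, feature
normalization, the classifier) are trained strictly in chain order on
training samples only; by default every sample is test data until a
splitter node assigns a stratified train/test split.

Key algorithms, in the field's standard notation:

- **xDAWN** spatial filtering: with evoked-response estimate `A` (mean of
  target epochs), signal covariance `R_s = AᵀA/T` and pooled noise
  covariance `R_x`, filters are the leading generalized eigenvectors of
  `R_s w = λ R_x w`.
- **CSP**: per-class mean of trace-normalized epoch covariances `Σ₁, Σ₂`;
  filters solve `Σ₁ w = λ (Σ₁+Σ₂) w`, retained alternately from both ends
  of the eigenvalue spectrum.
- **Classifier**: L2-regularized logistic regression minimizing
  `Σ log(1+exp(−yᵢ(w·xᵢ+b))) + ‖w‖²/(2C)`, with "complexity" `C` tunable
  by a grid-search meta node using stratified k-fold cross-validation on
  the training data only.

An **operation** expands a YAML node-chain template containing
`__token__` placeholders over the Cartesian product of parameter ranges
(with `range(a, b, s)` expressions and boolean constraints), creating one
independent process per (dataset × parameter binding × run index). The
run index seeds every randomized node, so results are exactly
reproducible. Processes execute on a serial or multicore back-end —
required to produce bit-identical results — and are consolidated into one
`results.csv` plus a spec archive and compressed process folders.

A synthetic oddball generator (white noise + a half-sine evoked
deflection on a random unit spatial pattern) makes the whole pipeline
testable without any recording.

## Worked example

```r
library(sigspace)

gen <- generate_oddball_stream(n_targets = 50, n_standards = 200,
                               amplitude = 2, noise_sigma = 1, seed = 7)
rules <- list(cutting_rule("Target", 0, 800, "Target"),
              cutting_rule("Standard", 0, 800, "Standard"))
epochs <- segment_by_markers(gen$stream, rules)
ds <- sp_dataset("time_series", epochs$windows)

chain <- read_node_chain(text = "
node_chain:
  - node: TimeSeriesSource
  - node: TrainTestSplitter
    parameters: {train_fraction: 0.5}
  - node: LowpassFilter
    parameters: {cutoff_hz: 4}
  - node: Decimation
    parameters: {factor: 8}
  - node: XDAWN
    parameters: {retained_channels: 4}
  - node: TimeDomainFeatures
  - node: FeatureNormalization
  - node: LinearClassifier
    parameters: {complexity: 1}
  - node: PerformanceSink
")
res <- run_node_chain(chain, ds, run_index = 0)
res$metrics$test
```

Output of this exact script:

```
windows: 250 dropped: 0
test: n=125 acc=0.984 balanced=0.960 precision=1.000 recall=0.920 F=0.958
train balanced accuracy: 1.000
```

250 epochs were cut (none crossed the stream boundary); half are held
out. After lowpass filtering, 8× decimation and xDAWN projection to 4
pseudo-channels, the logistic classifier separates Target from Standard
epochs on the unseen half with balanced accuracy 0.96 — Target recall
0.92 at perfect precision. The perfect training score (1.000) is the
usual optimistic training estimate, which is why metrics are always
reported for both phases.

To sweep spatial filters and channel counts over several datasets, write
the chain once as a template (`node: __alg__`,
`retained_channels: __channels__`), list the values under
`parameter_ranges`, and launch:

```r
launch("my_operation.yaml", mcore = TRUE)   # or Rscript + sigspace::launch
```

The time-stamped result folder contains `results.csv` with one row per
process (`Dataset`, `Run`, parameter columns, `Train_*`/`Test_*`
metrics), queryable with `query_results()`.

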