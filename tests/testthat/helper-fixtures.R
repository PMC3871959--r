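# Small in-code fixtures shared across test files.

# deterministic toy stream: linear ramp per channel, easy to slice by hand
toy_stream <- function(n = 1000L, channels = 3L, fs = 100,
                       markers = data.frame(sample_index = integer(),
                                            name = character())) {
  m <- outer(seq_len(n), seq_len(channels), function(i, j) i + 1000 * j)
  raw_stream(m, sprintf("ch%d", seq_len(channels)), fs, markers)
}

toy_window <- function(values, fs = 100, label = NULL) {
  values <- as.matrix(values)
  ts_window(values, sprintf("ch%d", seq_len(ncol(values))), fs, label = label)
}

# labelled gaussian windows with optional planted mean bump on channel 1
gaussian_windows <- function(n, tp = 20L, channels = 4L, label = "Standard",
                             bump = 0, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- matrix(rnorm(tp * channels), tp, channels)
    v[, 1] <- v[, 1] + bump
    toy_window(v, label = label)
  })
}

toy_feature_dataset <- function(n_per_class = 10L, d = 3L, sep = 4,
                                seed = 7L) {
  generate_gaussian_features(n_per_class, d, separation = sep, seed = seed)
}

fig_chain_text <- "
node_chain:
  - node: TimeSeriesSource
  - node: TrainTestSplitter
    parameters: {train_fraction: 0.5}
  - node: LowpassFilter
    parameters: {cutoff_hz: 4}
  - node: Decimation
    parameters: {factor: 8}
  - node: __alg__
    parameters: {retained_channels: __channels__}
  - node: TimeDomainFeatures
  - node: FeatureNormalization
  - node: LinearClassifier
    parameters: {complexity: 1}
  - node: PerformanceSink
"

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
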