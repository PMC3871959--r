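---
title: "Methods: node chains, spatial filters, and benchmarking semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: node chains, spatial filters, and benchmarking semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigspace)
```

This vignette is the package's own account of its methods: the processing
model and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, the numerical choices, and the
design decisions that were genuinely open.

## The processing model

sigspace treats an analysis as a chain of *nodes*, each mapping one data
sample to another. Samples exist at four granularities: a continuous
*raw stream* (samples × channels, with event markers), a *windowed time
series* (one epoch, rows = time points, columns = channels — this
orientation is fixed package-wide so spatial filtering is a plain matrix
product `X W`), a *feature vector*, and a *prediction*. A chain starts at
a source node feeding samples from a dataset and ends at a sink; a
performance sink computes confusion-matrix metrics separately for
training and test samples.

**Training protocol.** Nodes are trained strictly in chain order: each
trainable node sees the training samples as transformed by all upstream
(already trained) nodes, then all samples — train and test, flagged — are
pushed through. Until a splitter node runs, *every* sample is test data;
a trainable node that receives no training samples is an error rather
than a silent fallback. Unsupervised trainable nodes (PCA) also train on
training samples only, for uniformity: a green leakage test should not
depend on which node happens to be unsupervised.

**Determinism.** `(chain, dataset, run_index)` fully determines the
output. Each randomized node's seed is a stable 32-bit FNV-1a hash of
(run index, chain position, node name): the run index alone would make
two randomized nodes in one chain draw correlated streams, and R's
`set.seed` needs a value below 2³¹. All seeded code runs inside a
save/restore wrapper so a chain never perturbs the caller's RNG state.

## Segmentation conventions

Marker offsets are converted as `samples = round(ms · fs / 1000)` and
must land on whole samples — a silently shifted window boundary is the
kind of bug this refuses to have. A window for marker `m` spans the
half-open, 0-based sample range `[m + start, m + end)`, so its length is
exactly `end − start` samples. Windows crossing the stream boundary are
dropped and counted, never padded (padding fabricates data). A marker may
match several cutting rules; each match emits a window.

## Spatial filters

*xDAWN* estimates the evoked response as the mean `A` of the
target-class training epochs, forms `R_s = AᵀA/T` and the pooled noise
covariance `R_x` from all training epochs (per-epoch channel means
removed), and takes leading generalized eigenvectors of `(R_s, R_x)`.
For non-overlapping epochs the epoch-mean estimate equals the original
least-squares evoked-response estimate; for overlapping stimulus layouts
the two differ, which is a documented limitation — epochs here never
overlap within an inter-stimulus interval.

*CSP* averages trace-normalized epoch covariances per class and solves
`Σ₁ w = λ(Σ₁+Σ₂) w`. Both spectrum ends are informative, so filters are
retained alternately (1st, last, 2nd, 2nd-last, …) until the requested
count. Eigenvalues lie in (0, 1); values near 0.5 mean no variance
contrast.

*Numerics:* every covariance gets a ridge `1e-6 · trace/C` on the
diagonal before the (Cholesky-whitened, symmetric) eigendecomposition;
filters are unit-norm with a deterministic sign (largest-magnitude entry
positive), so repeated fits and channel-permuted fits agree up to the
mathematically unavoidable sign.

## Classifier and hyper-parameter search

The linear classifier is L2-regularized logistic regression,
`min Σ log(1+exp(−yᵢ(w·xᵢ+b))) + ‖w‖²/(2C)`, optimized by deterministic
BFGS from a zero start (analytic gradient, numerically stable
`log1p(exp(·))`). `C` is the inverse regularization strength, named
*complexity* as in SVM practice; the original design wraps an external
SVM, which is deliberately out of scope — logistic regression keeps the
grid-search example reproducible with zero external solvers while the
node contract leaves a drop-in slot for SVM wrappers. Scores `≥ 0` map
to the positive class; the tie at exactly 0 is assigned positively by
declared convention.

Grid search is a *meta node*: for each grid point the chain tail
(typically normalization + classifier) is retrained per stratified fold
and scored on the held-out fold; the best mean validation metric wins,
ties going to the earliest listed point (so a reported winner is always
reproducible from the listing order). The winning tail is retrained on
all training data. Test-flagged samples never enter any fold.

## Splitting

The stated train/test splitter is stratified and seeded. A per-class
`round(n_c · f)` rule has a subtle defect: at f = 0.5 with two classes
of 5, banker's rounding gives 2 + 2 = 4 training samples where "half of
the data" clearly means 5. The implementation therefore allocates the
*total* `round(n · f)` over classes by largest remainder, clamped so
every class keeps at least one sample on each side. k-fold assignment
deals shuffled per-class indices round-robin, so per-class fold sizes
differ by at most one; `k` may equal the smallest class size
(leave-one-out per stratum) but not exceed it.

## Operations, grids, constraints

A node-chain operation binds a YAML template with `__token__`
placeholders over the Cartesian product of parameter ranges, in
token-declaration order with the first token varying slowest — the
results table then sorts identically to the grid listing. Ranges accept
`range(a, b, s)` with the usual exclusive-upper-bound semantics
(`range(2, 63, 2)` → 2…62). Constraints are boolean combinations
(`and`/`or`/`not`, parentheses) of comparisons between tokens and
literals, evaluated by a small interpreter — never by `eval` — because a
spec file should not be able to execute code. The canonical use is
restricting a baseline: `__alg__ != "Noop" or __channels__ == 8`
collapses the channel sweep for the no-filter condition, whose result
cannot depend on it.

Each (dataset × binding × run) is an independent process; the run index
is its seed. Consolidation writes one `results.csv` row per successful
process (failures go to `failures.yaml` and never abort siblings),
archives the operation spec and template for replicability, and
compresses every process folder except the first, kept as an example.
Archives are `tar.gz` rather than zip: the execution environment
guarantees an internal tar implementation but no zip binary. Serial and
multicore back-ends are required to produce bit-identical
`results.csv`; the multicore back-end forks, each worker writing only
its own sub-path.

## The synthetic world

`generate_oddball_stream` emulates an oddball ERP recording: white
Gaussian noise per channel, stimuli in seeded random order at a fixed
inter-stimulus interval, and after each Target a half-sine deflection
(default latency 300 ms, width 200 ms, amplitude/σ = 2 — a strong but
realistic single-trial ERP signal-to-noise for a good P300 setup)
projected onto a random unit spatial pattern. Defaults (8 channels,
100 Hz, 50 targets / 200 standards, 1 s ISI) are the desk-scale
conditions the acceptance suite states. The half-sine shape was chosen
because its epoch mean has a closed form, so generator correctness is
testable by a law-of-large-numbers bound, and the optimal spatial filter
under white noise is the planted pattern itself — the xDAWN recovery
test compares against that closed form, not against the code under test.

What the generator does *not* emulate: pink/1-f noise, artifacts
(blinks, drift), volume-conduction structure in the noise, latency
jitter, overlapping responses. A green end-to-end test therefore
establishes the *machinery* (segmentation, training protocol, seeding,
parallel equivalence, metric plumbing) and the filters' behavior under
the stated model — not clinical-grade EEG performance.

`generate_gaussian_features` provides the feature-level analogue: two
isotropic Gaussian classes separated by `separation` along a seeded
random direction, giving a known Bayes accuracy (`Φ(separation/2)`) to
bracket classifier sanity checks (chance at 0, ≥ 0.95 at 6).

## Tolerances and degenerate inputs

Channel or feature standardization uses population standard deviation;
anything with spread below 1e-12 maps to zero rather than dividing by
noise. CSV floats serialize with 17 significant digits (doubles
round-trip bit-exactly). Readers reject silently-corrupting input —
ragged rows, non-numeric cells, duplicate names, out-of-range markers —
naming the offending line. Metric denominators that are empty yield 0 by
convention so the results table stays numeric; this is documented rather
than hidden because it affects precision/recall on degenerate folds.

## Known limitations

Binary classification only (the oddball setting is binary); vendor EEG
formats are out of scope (CSV streams only); online/streaming execution
is out of scope; cluster back-ends are not implemented, though the
back-end contract (descriptor in, outcome out, order-preserving) is the
extension point. The example chain's 4 Hz lowpass suits the planted
2.5 Hz evoked response; real P300 work would typically keep more band.
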