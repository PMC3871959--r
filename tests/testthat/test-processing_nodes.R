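# Algorithm library: preprocessing, spatial filters, features,
# normalization, classification, splitting, grid search.

test_that("standardize_window z-scores per channel with population sd", {
  w <- toy_window(cbind(c(2, 4, 6), c(5, 5, 5)))
  out <- standardize_window(w)
  expect_equal(out$values[, 1], c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(out$values[, 2], c(0, 0, 0))        # zero-variance rule
  set.seed(1)
  w2 <- toy_window(matrix(rnorm(50), 25, 2) * 3 + 2)
  out2 <- standardize_window(w2)
  expect_equal(colMeans(out2$values), c(0, 0), tolerance = 1e-12)
  expect_equal(sqrt(colMeans(out2$values^2)), c(1, 1), tolerance = 1e-12)
})

test_that("decimate_window averages blocks and rescales fs", {
  w <- toy_window(cbind(1:4, rep(7, 4)))
  out <- decimate_window(w, 2L)
  expect_equal(out$values[, 1], c(1.5, 3.5))
  expect_equal(out$values[, 2], c(7, 7))           # constants stay constant
  expect_equal(out$sampling_frequency, 50)
  expect_identical(decimate_window(w, 1L), w)      # factor 1 is identity
  expect_error(decimate_window(w, 0L), "positive")
  expect_error(decimate_window(w, 5L), "exceeds")
  # trailing partial block dropped: length floor(T/factor)
  expect_equal(nrow(decimate_window(toy_window(matrix(1:5)), 2L)$values), 2L)
})

test_that("lowpass filter passes the band, stops above, unity DC", {
  fs <- 100; cutoff <- 10
  t <- seq_len(400) / fs
  rms_mid <- function(x) sqrt(mean(x[100:300]^2))  # interior samples
  sin_in <- toy_window(matrix(sin(2 * pi * 1 * t)))     # 0.1 * cutoff
  out <- lowpass_filter_window(sin_in, cutoff)
  expect_equal(nrow(out$values), 400L)
  ratio <- rms_mid(out$values[, 1]) / rms_mid(sin_in$values[, 1])
  expect_gt(20 * log10(ratio), -1)                 # within 1 dB
  sin_hi <- toy_window(matrix(sin(2 * pi * 30 * t)))    # 3 * cutoff
  out_hi <- lowpass_filter_window(sin_hi, cutoff)
  atten <- 20 * log10(rms_mid(out_hi$values[, 1]) /
                        rms_mid(sin_hi$values[, 1]))
  expect_lt(atten, -20)                            # >= 20 dB attenuation
  dc <- toy_window(matrix(rep(3.5, 200)))
  expect_equal(lowpass_filter_window(dc, cutoff)$values[, 1],
               rep(3.5, 200), tolerance = 1e-9)    # unity DC gain
  expect_error(lowpass_filter_window(dc, 60), "fs/2")
})

test_that("xDAWN recovers an ERP confined to one channel", {
  # noise ~ isotropic, evoked response only on channel 1: the Rayleigh
  # quotient optimum is +/- e1
  set.seed(42)
  erp <- c(rep(0, 5), sin(pi * (1:10) / 10) * 3, rep(0, 5))
  make <- function(lab) {
    v <- matrix(rnorm(20 * 4), 20, 4)
    if (lab == "Target") v[, 1] <- v[, 1] + erp
    toy_window(v, label = lab)
  }
  train <- c(lapply(1:40, function(i) make("Target")),
             lapply(1:40, function(i) make("Standard")))
  model <- fit_xdawn(train, "Target", 2L)
  expect_equal(dim(model$filters), c(4L, 2L))
  expect_equal(sqrt(colSums(model$filters^2)), c(1, 1), tolerance = 1e-9)
  expect_gt(abs(cosine(model$filters[, 1], c(1, 0, 0, 0))), 0.99)
  expect_error(fit_xdawn(train, "Missing", 2L), "at least 2")
  expect_error(fit_xdawn(train, "Target", 9L), "retained_channels")
})

test_that("xDAWN with k = n_channels spans the data (invertible)", {
  set.seed(5)
  train <- gaussian_windows(10, label = "Target", bump = 1)
  model <- fit_xdawn(train, "Target", 4L)
  W <- model$filters
  w <- train[[1]]
  projected <- apply_spatial_filter(model, w)
  back <- projected$values %*% solve(W)
  expect_equal(back, w$values, tolerance = 1e-6)
})

test_that("CSP finds a planted variance direction; eigenvalues in (0,1)", {
  set.seed(11)
  v <- c(1, 2, -1, 0.5); v <- v / sqrt(sum(v^2))
  make <- function(lab) {
    z <- matrix(rnorm(50 * 4), 50, 4)
    if (lab == "A") z <- z + rnorm(50, sd = sqrt(9)) %o% v
    toy_window(z, label = lab)
  }
  train <- c(lapply(1:200, function(i) make("A")),
             lapply(1:200, function(i) make("B")))
  model <- fit_csp(train, 2L)
  expect_gt(abs(cosine(model$filters[, 1], v)), 0.95)
  expect_true(all(model$eigenvalues > 0 & model$eigenvalues < 1))
  # identical class distributions: eigenvalues concentrate near 0.5
  null_train <- c(lapply(1:150, function(i) {
    toy_window(matrix(rnorm(200), 50, 4), label = "A")
  }), lapply(1:150, function(i) {
    toy_window(matrix(rnorm(200), 50, 4), label = "B")
  }))
  m0 <- fit_csp(null_train, 2L)
  expect_lt(max(abs(m0$eigenvalues - 0.5)), 0.1)
  expect_error(fit_csp(train[1:200], 2L), "2 classes")
})

test_that("PCA filters align with the dominant axis and are orthonormal", {
  set.seed(2)
  u <- c(1, 1) / sqrt(2)
  train <- lapply(1:50, function(i) {
    z <- cbind(rnorm(40, sd = 3), rnorm(40, sd = 1))  # var 9 along x
    rot <- z %*% rbind(u, c(-u[2], u[1]))
    toy_window(rot)
  })
  model <- fit_pca(train, 2L)
  expect_gt(abs(cosine(model$filters[, 1], u)), 0.99)
  expect_equal(crossprod(model$filters), diag(2), tolerance = 1e-9)
  expect_true(all(diff(model$eigenvalues) <= 1e-9))  # non-increasing
})

test_that("spatial filters commute with channel permutation (up to sign)", {
  gen <- generate_oddball_stream(n_targets = 30L, n_standards = 90L,
                                 seed = 4)
  seg <- segment_by_markers(gen$stream,
                            list(cutting_rule("Target", 0, 800, "Target"),
                                 cutting_rule("Standard", 0, 800,
                                              "Standard")))
  train <- seg$windows
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  permute <- function(w) {
    w$values <- w$values[, perm]
    w$channel_names <- w$channel_names[perm]
    w
  }
  train_p <- lapply(train, permute)
  for (fit in list(function(tr) fit_xdawn(tr, "Target", 1L),
                   function(tr) fit_csp(tr, 1L),
                   function(tr) fit_pca(tr, 1L))) {
    w1 <- fit(train)$filters[, 1]
    w2 <- fit(train_p)$filters[, 1]
    expect_gt(abs(cosine(w1[perm], w2)), 1 - 1e-6)
  }
})

test_that("apply_spatial_filter is linear and renames channels", {
  model <- fit_pca(gaussian_windows(5, seed = 3), 2L)
  a <- gaussian_windows(1, seed = 10)[[1]]
  b <- gaussian_windows(1, seed = 11)[[1]]
  lin <- a; lin$values <- 2 * a$values + 3 * b$values
  out <- apply_spatial_filter(model, lin)
  expect_equal(out$values,
               2 * apply_spatial_filter(model, a)$values +
                 3 * apply_spatial_filter(model, b)$values,
               tolerance = 1e-9)
  expect_equal(out$channel_names, c("PCA00", "PCA01"))
  bad <- toy_window(matrix(0, 5, 2))
  expect_error(apply_spatial_filter(model, bad), "channels")
})

test_that("time-domain features flatten row-major with ms names", {
  w <- ts_window(rbind(c(1, 2), c(3, 4)), c("ch1", "ch2"), 100,
                 label = "Target")
  fv <- extract_time_features(w)
  expect_equal(fv$feature_names,
               c("TD_ch1_0.0", "TD_ch2_0.0", "TD_ch1_10.0", "TD_ch2_10.0"))
  expect_equal(fv$values, c(1, 2, 3, 4))          # values preserved in order
  expect_equal(fv$label, "Target")
  expect_length(extract_time_features(toy_window(matrix(0, 7, 3)))$values,
                21L)                               # T x C
})

test_that("feature normalization uses training moments", {
  train <- list(feature_vector(0, "f"), feature_vector(2, "f"))
  model <- fit_normalization(train)
  expect_equal(model$location, 1)
  expect_equal(model$scale, 1)                     # population sd of {0,2}
  expect_equal(apply_normalization(model, feature_vector(3, "f"))$values, 2)
  # after apply, training features have mean 0 sd 1
  set.seed(8)
  tr <- lapply(1:20, function(i)
    feature_vector(c(rnorm(1, 5, 2), 42), c("a", "const")))
  m <- fit_normalization(tr)
  norm <- vapply(tr, function(fv) apply_normalization(m, fv)$values,
                 numeric(2))
  expect_equal(mean(norm[1, ]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(norm[1, ]^2)), 1, tolerance = 1e-9)
  expect_equal(norm[2, ], rep(0, 20))              # constant feature -> 0
  expect_error(apply_normalization(m, feature_vector(1, "other")), "names")
  expect_error(fit_normalization(tr[1]), ">= 2")
})

test_that("linear classifier separates, is symmetric, shrinks with C", {
  sep <- list(feature_vector(c(-2, 0), c("x", "y"), label = "Standard"),
              feature_vector(c(-1, 1), c("x", "y"), label = "Standard"),
              feature_vector(c(2, 0), c("x", "y"), label = "Target"),
              feature_vector(c(1, -1), c("x", "y"), label = "Target"))
  model <- train_linear_classifier(sep, complexity = 1000)
  preds <- vapply(sep, function(fv) classify(model, fv)$assigned_label,
                  character(1))
  expect_equal(preds, vapply(sep, function(fv) fv$label, character(1)))
  # mirror-symmetric data about the origin: bias ~ 0
  expect_lt(abs(model$bias), 1e-6)
  # ||w|| shrinks monotonically as C -> 0 over a decade grid
  norms <- vapply(10^seq(2, -3), function(C) {
    m <- train_linear_classifier(sep, complexity = C)
    sqrt(sum(m$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_error(train_linear_classifier(sep[1:2], 1), "single class")
  expect_error(train_linear_classifier(sep, -1), "complexity")
})

test_that("classify scores and tie rule; sigmoid mapping is monotone", {
  model <- structure(list(weights = 1, bias = 0,
                          complexity = 1, class_labels = c("neg", "pos"),
                          feature_names = "x"), class = "linear_model")
  p <- classify(model, feature_vector(2, "x", label = "pos"))
  expect_equal(p$score, 2)
  expect_equal(p$assigned_label, "pos")
  expect_equal(classify(model, feature_vector(-2, "x"))$assigned_label,
               "neg")
  expect_equal(classify(model, feature_vector(0, "x"))$assigned_label,
               "pos")                              # score 0 -> positive
  expect_equal(map_score_sigmoid(p, 1)$score, 1 / (1 + exp(-2)))
  zero <- classify(model, feature_vector(0, "x"))
  expect_equal(map_score_sigmoid(zero, 3)$score, 0.5)
  scores <- c(-5, -0.1, 0, 0.3, 4)
  mapped <- vapply(scores, function(s) {
    pv <- prediction_vector(s, "pos")
    map_score_sigmoid(pv, 2)$score
  }, numeric(1))
  expect_true(all(diff(mapped) > 0))               # ranking preserved
})

test_that("stratified train/test split is balanced and seed-deterministic", {
  labels <- rep(c("A", "B"), each = 5)
  f <- split_train_test(labels, 0.5, seed = 1)
  expect_equal(sum(f == "train"), 5L)
  for (cls in c("A", "B")) {
    expect_setequal(unique(f[labels == cls]), c("train", "test"))
  }
  expect_identical(f, split_train_test(labels, 0.5, seed = 1))
  big <- rep(c("A", "B"), each = 50)
  expect_false(identical(split_train_test(big, 0.5, 0),
                         split_train_test(big, 0.5, 1)))
  expect_error(split_train_test(c("A", "A", "B"), 0.5, 0), "single sample")
  # clamping: every class keeps >= 1 train and >= 1 test
  f2 <- split_train_test(rep(c("A", "B"), each = 2), 0.9, seed = 0)
  for (cls in c("A", "B"))
    expect_setequal(f2[rep(c("A", "B"), each = 2) == cls],
                    c("train", "test"))
})

test_that("stratified k-fold folds are disjoint, exhaustive, balanced", {
  labels <- rep(c("A", "B"), each = 10)
  folds <- kfold_splits(labels, 5, seed = 2)
  expect_setequal(unique(folds), 1:5)
  for (i in 1:5) {
    expect_equal(sum(folds == i), 4L)              # folds of 4
    expect_equal(sum(folds == i & labels == "A"), 2L)  # 2 per class
  }
  expect_identical(folds, kfold_splits(labels, 5, seed = 2))
  expect_error(kfold_splits(labels, 11, seed = 0), "smallest class")
  # leave-one-out boundary: k equal to the smallest class size is allowed
  loo <- kfold_splits(rep(c("A", "B"), each = 3), 3, seed = 0)
  expect_setequal(unique(loo), 1:3)
})

test_that("grid search reproduces brute-force fold means and tie rule", {
  ds <- generate_gaussian_features(20L, 3L, separation = 3, seed = 9)
  train <- ds$samples
  tail_spec <- list(list(node = "LinearClassifier",
                         parameters = list(complexity = "__C__",
                                           class_labels = list("Standard",
                                                               "Target"))))
  res <- grid_search(tail_spec, grid = list(`__C__` = list(0.01, 1, 100)),
                     k = 5L, metric = "balanced_accuracy", train = train,
                     seed = 3L, positive_class = "Target")
  # brute force outside the node: same folds, same training path
  labels <- vapply(train, function(s) s$label, character(1))
  folds <- kfold_splits(labels, 5L, seed = 3L)
  brute <- vapply(c(0.01, 1, 100), function(C) {
    mean(vapply(1:5, function(fi) {
      m <- train_linear_classifier(train[folds != fi], complexity = C,
                                   class_labels = c("Standard", "Target"))
      preds <- lapply(train[folds == fi], function(s) classify(m, s))
      compute_metrics(preds, "Target")$balanced_accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_equal(res$scores, brute, tolerance = 1e-12)
  expect_equal(res$best$`__C__`, c(0.01, 1, 100)[which.max(brute)])
  # single-point grid: that point selected without CV
  one <- grid_search(tail_spec, grid = list(`__C__` = list(7)), k = 5L,
                     train = train, seed = 0L)
  expect_equal(one$best$`__C__`, 7)
  # tie -> earliest listed wins (identical duplicated grid values)
  tie <- grid_search(tail_spec, grid = list(`__C__` = list(1, 1)), k = 5L,
                     train = train, seed = 3L)
  expect_equal(res$scores[2], tie$scores[1])
  expect_identical(which.max(tie$scores), 1L)
})

test_that("trainable node apply is idempotent and input is not mutated", {
  train <- gaussian_windows(6, label = "Target", bump = 2, seed = 6)
  model <- fit_xdawn(train, "Target", 2L)
  w <- train[[1]]
  snapshot <- unserialize(serialize(w, NULL))
  once <- apply_spatial_filter(model, w)
  expect_identical(w, snapshot)                    # purity
  # idempotence at apply time: same result on a fresh copy
  again <- apply_spatial_filter(model, snapshot)
  expect_identical(once, again)
})
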