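# Algorithm primitives.  These are the pure functions behind the processing
# nodes: temporal preprocessing, spatial filtering, feature generation,
# normalization, linear classification and data splitting.  All of them are
# deterministic given their inputs (splitters take an explicit seed).

# --- temporal preprocessing -------------------------------------------------

#' Standardize each channel of a window
#'
#' Subtracts the channel mean and divides by the population standard
#' deviation; a channel with standard deviation below `1e-12` becomes all
#' zeros.
#'
#' @param w a [ts_window()].
#' @return a [ts_window()] of identical shape.
#' @export
standardize_window <- function(w) {
  stopifnot(inherits(w, "ts_window"))
  v <- w$values
  mu <- colMeans(v)
  sd_pop <- sqrt(colMeans(sweep(v, 2L, mu)^2))
  out <- sweep(v, 2L, mu)
  for (j in seq_along(sd_pop)) {
    out[, j] <- if (sd_pop[j] < 1e-12) 0 else out[, j] / sd_pop[j]
  }
  w$values <- out
  w
}

#' Downsample a window by block averaging
#'
#' Consecutive blocks of `factor` samples are replaced by their mean; the
#' sampling frequency is divided by `factor` and a trailing partial block is
#' discarded.
#'
#' @param w a [ts_window()].
#' @param factor integer decimation factor `>= 1`, at most the window
#'   length.
#' @return the decimated [ts_window()].
#' @export
decimate_window <- function(w, factor) {
  stopifnot(inherits(w, "ts_window"))
  if (!is_count(factor)) stop_sigspace("factor must be a positive integer")
  factor <- as.integer(factor)
  n <- nrow(w$values)
  if (factor > n) stop_sigspace("decimation factor exceeds window length")
  if (factor == 1L) return(w)
  nb <- n %/% factor
  idx <- rep(seq_len(nb), each = factor)
  v <- w$values[seq_len(nb * factor), , drop = FALSE]
  out <- apply(v, 2L, function(col) tapply(col, idx, mean))
  if (nb == 1L) out <- matrix(out, nrow = 1L)
  w$values <- unname(as.matrix(out))
  w$sampling_frequency <- w$sampling_frequency / factor
  w
}

fir_lowpass_taps <- function(cutoff_hz, fs) {
  ntaps <- ceiling(4 * fs / cutoff_hz)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  ntaps <- max(ntaps, 5)
  m <- (ntaps - 1) / 2
  k <- seq_len(ntaps) - 1
  fc <- cutoff_hz / fs                       # normalized cutoff (cycles/sample)
  x <- k - m
  h <- ifelse(x == 0, 2 * fc, sin(2 * pi * fc * x) / (pi * x))
  ham <- 0.54 - 0.46 * cos(2 * pi * k / (ntaps - 1))
  h <- h * ham
  h / sum(h)                                 # unity DC gain
}

#' Lowpass-filter each channel with a linear-phase FIR
#'
#' A windowed-sinc (Hamming) filter with the smallest odd tap count of at
#' least `4 * fs / cutoff_hz` is applied per channel.  Reflect padding plus
#' group-delay compensation keep the output length equal to the input
#' length; DC gain is exactly one.
#'
#' @param w a [ts_window()].
#' @param cutoff_hz cutoff frequency, `0 < cutoff_hz < fs / 2`.
#' @return the filtered [ts_window()].
#' @export
lowpass_filter_window <- function(w, cutoff_hz) {
  stopifnot(inherits(w, "ts_window"))
  fs <- w$sampling_frequency
  if (!is_number(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop_sigspace("cutoff must lie in (0, fs/2)")
  h <- fir_lowpass_taps(cutoff_hz, fs)
  m <- (length(h) - 1) / 2
  n <- nrow(w$values)
  if (m > n - 1)
    stop_sigspace("window too short (%d samples) for a %d-tap filter",
                  n, length(h))
  out <- w$values
  for (j in seq_len(ncol(out))) {
    x <- w$values[, j]
    padded <- c(rev(x[2:(m + 1)]), x, rev(x[(n - m):(n - 1)]))
    # 'filter' convolution keeps the valid part: length(padded) - 2m = n
    y <- stats::convolve(padded, h, type = "filter")
    out[, j] <- y
  }
  w$values <- out
  w
}

# --- spatial filters --------------------------------------------------------

new_spatial_filter <- function(filters, method) {
  k <- ncol(filters)
  # unit-norm columns, deterministic sign: largest-|entry| positive
  for (j in seq_len(k)) {
    v <- filters[, j]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    filters[, j] <- v
  }
  structure(
    list(filters = filters,
         output_channel_names = sprintf("%s%02d", method, seq_len(k) - 1L),
         method = method),
    class = "spatial_filter_model"
  )
}

# symmetric generalized eigenproblem A w = lambda B w via Cholesky whitening
generalized_eigen <- function(A, B) {
  L <- tryCatch(chol(B), error = function(e)
    stop_sigspace("covariance matrix singular after regularization"))
  Linv <- backsolve(L, diag(nrow(B)))
  M <- t(Linv) %*% A %*% Linv
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  list(values = e$values, vectors = Linv %*% e$vectors)
}

ridge_regularize <- function(S) {
  C <- nrow(S)
  S + diag(1e-6 * sum(diag(S)) / C, C)
}

#' Fit xDAWN spatial filters for evoked-response enhancement
#'
#' Estimates the evoked response as the mean of the target-class training
#' windows, forms the signal covariance `R_s = A'A / T` from that mean `A`
#' and the noise covariance `R_x` as the pooled covariance of all training
#' windows (per-window channel means removed, ridge-regularized), and takes
#' the top `retained_channels` generalized eigenvectors of `(R_s, R_x)`.
#' With non-overlapping epochs the epoch-mean estimate coincides with the
#' least-squares evoked-response estimate of the original formulation.
#'
#' @param train list of labelled [ts_window()] objects, all of one shape.
#' @param target_label class whose evoked response is to be enhanced; at
#'   least two windows of this class are required.
#' @param retained_channels number of filters to keep, `<=` channel count.
#' @return a `spatial_filter_model`.
#' @export
fit_xdawn <- function(train, target_label, retained_channels) {
  tgt <- Filter(function(w) identical(w$label, target_label), train)
  if (length(tgt) < 2L)
    stop_sigspace("xDAWN needs at least 2 '%s' windows", target_label)
  C <- ncol(train[[1]]$values)
  if (!is_count(retained_channels) || retained_channels > C)
    stop_sigspace("retained_channels must be in 1..%d", C)
  A <- Reduce(`+`, lapply(tgt, function(w) w$values)) / length(tgt)
  Tn <- nrow(A)
  Rs <- crossprod(A) / Tn
  Rx <- matrix(0, C, C)
  for (w in train) {
    X <- sweep(w$values, 2L, colMeans(w$values))
    Rx <- Rx + crossprod(X)
  }
  Rx <- ridge_regularize(Rx / (length(train) * Tn))
  ge <- generalized_eigen(Rs, Rx)
  new_spatial_filter(ge$vectors[, seq_len(retained_channels), drop = FALSE],
                     "xDAWN")
}

#' Fit common spatial patterns (CSP) for two-class variance contrast
#'
#' Per class, window covariances (channel means removed) are trace
#' normalized and averaged; the generalized eigenproblem
#' `S1 w = lambda (S1 + S2) w` is solved with eigenvalues sorted in
#' descending order, and filters are retained alternately from the two ends
#' of the spectrum (1st, last, 2nd, 2nd-last, ...).
#'
#' @param train list of labelled [ts_window()] objects covering exactly two
#'   classes; every window needs at least two time points.
#' @param retained_channels number of filters to keep.
#' @return a `spatial_filter_model`.
#' @export
fit_csp <- function(train, retained_channels) {
  labels <- vapply(train, function(w) w$label %||% NA_character_, character(1))
  classes <- sort(unique(labels))
  if (length(classes) != 2L || anyNA(labels))
    stop_sigspace("CSP requires exactly 2 classes, got %d", length(classes))
  C <- ncol(train[[1]]$values)
  if (!is_count(retained_channels) || retained_channels > C)
    stop_sigspace("retained_channels must be in 1..%d", C)
  class_cov <- function(cls) {
    ws <- train[labels == cls]
    S <- matrix(0, C, C)
    for (w in ws) {
      if (nrow(w$values) < 2L) stop_sigspace("window too short for covariance")
      X <- sweep(w$values, 2L, colMeans(w$values))
      Sw <- crossprod(X) / nrow(X)
      S <- S + Sw / sum(diag(Sw))
    }
    S / length(ws)
  }
  S1 <- class_cov(classes[1])
  S2 <- class_cov(classes[2])
  ge <- generalized_eigen(S1, ridge_regularize(S1 + S2))
  ord <- order(ge$values, decreasing = TRUE)
  # alternate ends: most class-1-dominant, most class-2-dominant, ...
  pick <- integer(retained_channels)
  lo <- 1L; hi <- C
  for (i in seq_len(retained_channels)) {
    if (i %% 2L == 1L) { pick[i] <- ord[lo]; lo <- lo + 1L }
    else { pick[i] <- ord[hi]; hi <- hi - 1L }
  }
  model <- new_spatial_filter(ge$vectors[, pick, drop = FALSE], "CSP")
  model$eigenvalues <- ge$values[ord]
  model
}

#' Fit PCA spatial filters on pooled channel covariance
#'
#' All training time points are pooled (channel means removed) and the top
#' `retained_channels` eigenvectors of the resulting channel covariance are
#' used as filters.
#'
#' @param train list of [ts_window()] objects.
#' @param retained_channels number of components to keep.
#' @return a `spatial_filter_model`.
#' @export
fit_pca <- function(train, retained_channels) {
  C <- ncol(train[[1]]$values)
  if (!is_count(retained_channels) || retained_channels > C)
    stop_sigspace("retained_channels must be in 1..%d", C)
  X <- do.call(rbind, lapply(train, function(w) w$values))
  X <- sweep(X, 2L, colMeans(X))
  S <- crossprod(X) / nrow(X)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  model <- new_spatial_filter(
    e$vectors[, seq_len(retained_channels), drop = FALSE], "PCA")
  model$eigenvalues <- e$values
  model
}

#' Identity spatial filter (no-operation baseline)
#'
#' @param channel_names channel names of the data the model will be applied
#'   to.
#' @return a `spatial_filter_model` that returns its input unchanged.
#' @export
fit_noop_filter <- function(channel_names) {
  structure(
    list(filters = diag(length(channel_names)),
         output_channel_names = channel_names, method = "noop"),
    class = "spatial_filter_model"
  )
}

#' Project a window onto spatial-filter pseudo-channels
#'
#' @param model a `spatial_filter_model` from one of the `fit_*` functions.
#' @param w a [ts_window()] with the channel count the model was trained on.
#' @return a [ts_window()] with `k` pseudo-channel columns (`values %*%
#'   filters`); a noop model returns the input unchanged.
#' @export
apply_spatial_filter <- function(model, w) {
  stopifnot(inherits(model, "spatial_filter_model"), inherits(w, "ts_window"))
  if (model$method == "noop") return(w)
  if (ncol(w$values) != nrow(model$filters))
    stop_sigspace("window has %d channels, filter expects %d",
                  ncol(w$values), nrow(model$filters))
  w$values <- w$values %*% model$filters
  w$channel_names <- model$output_channel_names
  w
}

# --- feature generation and normalization -----------------------------------

#' Flatten a window into time-domain amplitude features
#'
#' Row-major flattening (time point by time point); feature
#' `TD_<channel>_<time_ms>` holds the amplitude of that channel at that
#' time (ms from window start).  The window label is copied.
#'
#' @param w a [ts_window()].
#' @return a [feature_vector()] of length `n_timepoints * n_channels`.
#' @export
extract_time_features <- function(w) {
  stopifnot(inherits(w, "ts_window"))
  tms <- (seq_len(nrow(w$values)) - 1L) * 1000 / w$sampling_frequency
  names_grid <- as.vector(t(outer(
    tms, w$channel_names,
    function(t, ch) sprintf("TD_%s_%.1f", ch, t))))
  # row-major: all channels of time point 1, then time point 2, ...
  feature_vector(as.vector(t(w$values)), names_grid, label = w$label)
}

#' Learn per-feature location and scale from training vectors
#'
#' @param train list of [feature_vector()] objects (at least two).
#' @return a `normalization_model` holding the training mean and population
#'   standard deviation per feature.
#' @export
fit_normalization <- function(train) {
  if (length(train) < 2L) stop_sigspace("need >= 2 training vectors")
  X <- do.call(rbind, lapply(train, function(fv) fv$values))
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  structure(
    list(location = mu, scale = sd_pop,
         feature_names = train[[1]]$feature_names),
    class = "normalization_model"
  )
}

#' Apply a learned z-score normalization to one feature vector
#'
#' Features whose training standard deviation is below `1e-12` map to zero.
#'
#' @param model a `normalization_model`.
#' @param fv a [feature_vector()] with the model's feature names.
#' @return the normalized [feature_vector()].
#' @export
apply_normalization <- function(model, fv) {
  stopifnot(inherits(model, "normalization_model"),
            inherits(fv, "feature_vector"))
  if (!identical(fv$feature_names, model$feature_names))
    stop_sigspace("feature names do not match the normalization model")
  v <- fv$values - model$location
  v <- ifelse(model$scale < 1e-12, 0, v / pmax(model$scale, 1e-300))
  fv$values <- v
  fv
}

# --- classification ---------------------------------------------------------

#' Train an L2-regularized logistic-regression classifier
#'
#' Minimizes `sum(log(1 + exp(-y_i (w.x_i + b)))) + ||w||^2 / (2C)` with
#' labels `y` in `{-1, +1}` following the order of `class_labels`
#' (negative class first).  `C` is the inverse regularization strength
#' ("complexity": large `C` means a hard fit).  Optimization is
#' deterministic BFGS from a zero start.
#'
#' @param train list of labelled [feature_vector()] objects covering both
#'   classes.
#' @param complexity positive `C`.
#' @param class_labels character pair `(negative, positive)`; defaults to
#'   the sorted labels present.
#' @return a `linear_model` with fields `weights`, `bias`, `complexity`,
#'   `class_labels`, `feature_names`.
#' @export
train_linear_classifier <- function(train, complexity = 1,
                                    class_labels = NULL) {
  if (!is_number(complexity) || complexity <= 0)
    stop_sigspace("complexity must be > 0")
  labels <- vapply(train, function(fv) fv$label %||% NA_character_,
                   character(1))
  if (anyNA(labels)) stop_sigspace("all training vectors must be labelled")
  present <- sort(unique(labels))
  if (is.null(class_labels)) class_labels <- present
  if (length(present) < 2L)
    stop_sigspace("training data contains a single class ('%s')", present[1])
  if (!setequal(present, class_labels))
    stop_sigspace("labels (%s) do not match class_labels (%s)",
                  paste(present, collapse = ","),
                  paste(class_labels, collapse = ","))
  X <- do.call(rbind, lapply(train, function(fv) fv$values))
  y <- ifelse(labels == class_labels[2], 1, -1)
  d <- ncol(X)
  obj <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1L]
    z <- -y * (X %*% w + b)
    # numerically stable log(1 + exp(z))
    sum(pmax(z, 0) + log1p(exp(-abs(z)))) + sum(w^2) / (2 * complexity)
  }
  grad <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1L]
    z <- as.vector(X %*% w + b)
    s <- -y / (1 + exp(y * z))
    c(as.vector(t(X) %*% s) + w / complexity, sum(s))
  }
  fit <- stats::optim(rep(0, d + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  structure(
    list(weights = fit$par[seq_len(d)], bias = fit$par[d + 1L],
         complexity = complexity, class_labels = class_labels,
         feature_names = train[[1]]$feature_names),
    class = "linear_model"
  )
}

#' Score one feature vector with a trained linear model
#'
#' The decision value is `w.x + b`; the positive class is assigned when the
#' score is `>= 0` (a score of exactly zero goes to the positive class).
#'
#' @param model a `linear_model`.
#' @param fv a [feature_vector()].
#' @return a [prediction_vector()] carrying the sample's true label.
#' @export
classify <- function(model, fv) {
  stopifnot(inherits(model, "linear_model"), inherits(fv, "feature_vector"))
  if (!identical(fv$feature_names, model$feature_names))
    stop_sigspace("feature names do not match the classifier")
  score <- sum(model$weights * fv$values) + model$bias
  prediction_vector(
    score,
    assigned_label = if (score >= 0) model$class_labels[2]
                     else model$class_labels[1],
    true_label = fv$label,
    classifier_name = "LinearClassifier"
  )
}

#' Map a decision value through a logistic sigmoid
#'
#' `score' = 1 / (1 + exp(-scale * score))`; monotone, so rankings are
#' preserved and the assigned label is unchanged.
#'
#' @param p a [prediction_vector()].
#' @param scale positive steepness.
#' @return the mapped [prediction_vector()].
#' @export
map_score_sigmoid <- function(p, scale = 1) {
  stopifnot(inherits(p, "prediction_vector"))
  if (!is_number(scale) || scale <= 0) stop_sigspace("scale must be > 0")
  p$score <- 1 / (1 + exp(-scale * p$score))
  p
}

# --- splitting --------------------------------------------------------------

#' Stratified train/test split
#'
#' The total training count is `round(n * train_fraction)`, allocated to
#' the classes by largest remainder (so a 5/5 split at fraction 0.5 gives
#' exactly 5 training samples) and clamped so that every class keeps at
#' least one training and one test sample.  Within each class, membership
#' is decided by a seeded shuffle.
#'
#' @param labels character vector of class labels, every class with `>= 2`
#'   samples.
#' @param train_fraction fraction in `(0, 1)`.
#' @param seed integer seed; the assignment is a pure function of
#'   `(labels, train_fraction, seed)`.
#' @return character vector of `"train"` / `"test"` flags, one per sample.
#' @export
split_train_test <- function(labels, train_fraction = 0.5, seed = 0L) {
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop_sigspace("train_fraction must lie in (0, 1)")
  flags <- rep("test", length(labels))
  classes <- sort(unique(labels))
  sizes <- vapply(classes, function(cls) sum(labels == cls), integer(1))
  if (any(sizes < 2L))
    stop_sigspace("class '%s' has a single sample; cannot split",
                  classes[which(sizes < 2L)[1]])
  # largest-remainder allocation of the total training count over classes
  total <- max(1L, min(round(length(labels) * train_fraction + 1e-9),
                       length(labels) - 1L))
  base <- pmin(pmax(floor(sizes * train_fraction), 1L), sizes - 1L)
  n_train <- base
  frac <- sizes * train_fraction - floor(sizes * train_fraction)
  for (i in order(frac, decreasing = TRUE)) {
    if (sum(n_train) >= total) break
    if (n_train[i] < sizes[i] - 1L) n_train[i] <- n_train[i] + 1L
  }
  with_seed(seed, {
    for (i in seq_along(classes)) {
      idx <- which(labels == classes[i])
      flags[idx[sample.int(length(idx))][seq_len(n_train[i])]] <- "train"
    }
  })
  flags
}

#' Stratified k-fold assignment
#'
#' Per class, indices are shuffled with the seed and dealt round-robin over
#' the folds, so per-class fold sizes differ by at most one.  Fold `i` is
#' the validation set of split `i`.
#'
#' @param labels character vector of class labels.
#' @param k number of folds, `2 <= k <=` smallest class size.
#' @param seed integer seed.
#' @return integer vector of fold indices in `1..k`, one per sample.
#' @export
kfold_splits <- function(labels, k, seed = 0L) {
  if (!is_count(k, min = 2L)) stop_sigspace("k must be an integer >= 2")
  counts <- table(labels)
  if (k > min(counts))
    stop_sigspace("k = %d exceeds smallest class size %d", k, min(counts))
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      shuffled <- idx[sample.int(length(idx))]
      folds[shuffled] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
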