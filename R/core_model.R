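#' Interaction feature sets
#'
#' A feature is a set of neuron indices defining one product term
#' \eqn{\prod_{i \in F} x_i} in the exponent of a log-linear model; its order
#' is the number of neurons involved. A feature set is an ordered collection
#' of distinct features over N neurons. Neuron indices are 1-based.
#'
#' @param features List of integer vectors (each a set of neuron indices).
#' @param n_neurons Number of neurons N.
#' @return An object of class `feature_set` with elements `features`
#'   (sorted integer vectors) and `n_neurons`.
#' @examples
#' fs <- feature_set(list(1, 2, c(1, 2)), n_neurons = 2)
#' feature_orders(fs)
#' @export
feature_set <- function(features, n_neurons) {
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 1L) stop("n_neurons must be >= 1")
  feats <- lapply(features, function(f) {
    f <- as.integer(f)
    if (length(f) < 1L) stop("features must contain at least one neuron")
    if (anyDuplicated(f)) stop("feature indices must be unique")
    if (any(f < 1L) || any(f > n_neurons)) {
      stop("feature indices must lie in 1..n_neurons")
    }
    sort(f)
  })
  keys <- feature_keys_internal(feats)
  if (anyDuplicated(keys)) stop("duplicate features in feature set")
  structure(list(features = feats, n_neurons = n_neurons),
            class = "feature_set")
}

feature_keys_internal <- function(features) {
  vapply(features, function(f) sum(2^(f - 1L)), numeric(1))
}

#' @export
print.feature_set <- function(x, ...) {
  ord <- feature_orders(x)
  cat(sprintf("feature_set: %d features over %d neurons\n",
              length(x$features), x$n_neurons))
  if (length(ord)) print(table(order = ord))
  invisible(x)
}

#' @export
length.feature_set <- function(x) length(x$features)

#' Orders (sizes) of the features in a feature set
#'
#' @param fs A `feature_set` (or plain list of index vectors).
#' @return Integer vector of feature orders.
#' @export
feature_orders <- function(fs) {
  feats <- if (inherits(fs, "feature_set")) fs$features else fs
  lengths(feats)
}

#' Maximum entropy model with arbitrary-order interactions
#'
#' The model assigns each binary pattern x the probability
#' \deqn{P(x) = \frac{1}{Z}\exp\Big\{\sum_F \theta_F \prod_{i\in F} x_i\Big\},}
#' with one interaction parameter per feature and partition function Z.
#' `log_z` is optional: it may be computed exactly ([exact_log_partition()]),
#' estimated ([good_turing_log_partition()], [gibbs_silent_state_log_partition()]),
#' or left unset, in which case only unnormalized weights are available.
#'
#' @param n_neurons Number of neurons N.
#' @param features A `feature_set` (or list of index vectors).
#' @param theta Numeric vector of interaction parameters, one per feature.
#' @param log_z Optional log partition function.
#' @param z_method How `log_z` was obtained: one of `"exact"`,
#'   `"good_turing"`, `"gibbs_silent_state"`, `"none"`.
#' @return An object of class `maxent_model`.
#' @examples
#' m <- maxent_model(2, list(1, 2), theta = c(-1, -1))
#' log_weight(m, c(1, 0))
#' @export
maxent_model <- function(n_neurons, features, theta, log_z = NULL,
                         z_method = c("none", "exact", "good_turing",
                                      "gibbs_silent_state")) {
  z_method <- match.arg(z_method)
  fs <- if (inherits(features, "feature_set")) features else
    feature_set(features, n_neurons)
  if (fs$n_neurons != n_neurons) stop("feature set / n_neurons mismatch")
  theta <- as.numeric(theta)
  if (length(theta) != length(fs$features)) {
    stop("need exactly one theta per feature")
  }
  if (any(!is.finite(theta))) stop("theta must be finite")
  if (!is.null(log_z) && z_method == "none") z_method <- "exact"
  structure(list(n_neurons = as.integer(n_neurons), features = fs$features,
                 theta = theta, log_z = log_z, z_method = z_method),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d neurons, %d features (orders %s), z: %s\n",
              x$n_neurons, length(x$features),
              paste(range(lengths(x$features)), collapse = "-"),
              if (is.null(x$log_z)) "unset" else
                sprintf("log Z = %.4f (%s)", x$log_z, x$z_method)))
  invisible(x)
}

check_patterns_arg <- function(pattern, n_neurons) {
  if (is.null(dim(pattern))) {
    if (length(pattern) != n_neurons) {
      stop(sprintf("pattern has %d entries but the model has %d neurons",
                   length(pattern), n_neurons))
    }
    pattern <- matrix(pattern, nrow = 1L)
  }
  if (ncol(pattern) != n_neurons) {
    stop(sprintf("patterns have %d columns but the model has %d neurons",
                 ncol(pattern), n_neurons))
  }
  if (any(!(pattern == 0 | pattern == 1))) stop("patterns must be binary")
  storage.mode(pattern) <- "numeric"
  pattern
}

feature_activity <- function(patterns, features) {
  # m x F indicator: feature f active in pattern row iff all its neurons spike
  m <- nrow(patterns)
  out <- matrix(0, m, length(features))
  for (k in seq_along(features)) {
    f <- features[[k]]
    out[, k] <- if (length(f) == 1L) patterns[, f] else
      as.numeric(rowSums(patterns[, f, drop = FALSE]) == length(f))
  }
  out
}

#' Log of the unnormalized pattern weight
#'
#' Returns \eqn{\sum_F \theta_F \prod_{i\in F} x_i}, the exponent of the model
#' before normalization. The silent (all-zero) pattern always has log-weight 0.
#'
#' @param model A `maxent_model` (or `ri_model`, which shares the log-linear
#'   form).
#' @param pattern A 0/1 vector of length N, or a matrix with one pattern per
#'   row.
#' @return Numeric vector of log-weights, one per pattern.
#' @export
log_weight <- function(model, pattern) {
  p <- check_patterns_arg(pattern, model$n_neurons)
  drop(feature_activity(p, model$features) %*% model$theta)
}

# log-weights for all 2^N patterns, in key order 0..2^N-1, without
# materializing the pattern matrix: per-feature bitmask tests on keys.
all_pattern_log_weights <- function(model) {
  n <- model$n_neurons
  keys <- 0:(2^n - 1)
  logw <- numeric(2^n)
  for (k in seq_along(model$features)) {
    mask <- sum(bitwShiftL(1L, model$features[[k]] - 1L))
    logw[bitwAnd(keys, mask) == mask] <- logw[bitwAnd(keys, mask) == mask] +
      model$theta[k]
  }
  logw
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Exact log partition function by brute-force enumeration
#'
#' Sums the unnormalized weights of all 2^N patterns. Guarded at N <= 25;
#' beyond that, use [good_turing_log_partition()] or
#' [gibbs_silent_state_log_partition()].
#'
#' @param model A `maxent_model`.
#' @return log Z.
#' @examples
#' m <- maxent_model(4, list(1, 2, 3, 4), rep(0, 4))
#' exact_log_partition(m)  # log(16)
#' @export
exact_log_partition <- function(model) {
  if (model$n_neurons > 25L) {
    stop("exact partition function requires N <= 25 (2^N terms); ",
         "use good_turing_log_partition() or ",
         "gibbs_silent_state_log_partition() instead")
  }
  log_sum_exp(all_pattern_log_weights(model))
}

#' Attach a log partition function to a model
#'
#' @param model A `maxent_model`.
#' @param log_z Log partition value.
#' @param z_method Label recording how it was obtained.
#' @return The model with `log_z` and `z_method` set.
#' @export
set_log_partition <- function(model, log_z,
                              z_method = c("exact", "good_turing",
                                           "gibbs_silent_state")) {
  model$log_z <- as.numeric(log_z)
  model$z_method <- match.arg(z_method)
  model
}

#' Normalized pattern probability under a maximum entropy model
#'
#' @param model A `maxent_model` with `log_z` set.
#' @param pattern A 0/1 vector or matrix of patterns (rows).
#' @return Probabilities `exp(log_weight - log_z)`.
#' @export
pattern_probability <- function(model, pattern) {
  if (is.null(model$log_z)) {
    stop("model has no log_z; compute one with exact_log_partition(), ",
         "good_turing_log_partition() or gibbs_silent_state_log_partition()")
  }
  exp(log_weight(model, pattern) - model$log_z)
}

#' Uncentered empirical moments of a raster
#'
#' For binary data the uncentered moment of a neuron subset F equals the
#' marginal probability that all neurons in F spike in the same bin:
#' \eqn{\langle \prod_{i\in F} x_i \rangle = P(x_i = 1 \,\forall i \in F)}.
#'
#' @param raster A `spike_raster` (or binary matrix) with at least one row.
#' @param features A `feature_set` or list of index vectors.
#' @return Named-free numeric vector of moments in \[0, 1\], one per feature.
#' @export
empirical_moments <- function(raster, features) {
  x <- as_raster_matrix(raster)
  feats <- if (inherits(features, "feature_set")) features$features else features
  if (length(feats) == 0L) return(numeric(0))
  if (max(unlist(feats)) > ncol(x)) stop("feature index exceeds neuron count")
  storage.mode(x) <- "numeric"
  colMeans(feature_activity(x, feats))
}

#' Uncentered moments of a distribution object
#'
#' @param dist An `empirical_dist`.
#' @param features A `feature_set` or list of index vectors.
#' @return Numeric vector of moments.
#' @export
distribution_moments <- function(dist, features) {
  feats <- if (inherits(features, "feature_set")) features$features else features
  if (length(feats) == 0L) return(numeric(0))
  act <- feature_activity(matrix(as.numeric(dist$patterns),
                                 nrow = nrow(dist$patterns)), feats)
  drop(crossprod(act, dist$counts)) / dist$n_samples
}

#' Exact model moments by enumeration
#'
#' Expectation of each feature product under the normalized model, computed by
#' summing over all 2^N patterns (N <= 25). Serves as the oracle against which
#' fitted moments are validated.
#'
#' @param model A `maxent_model`.
#' @param features A `feature_set` or list of index vectors.
#' @return Numeric vector of exact moments.
#' @export
model_moments_exact <- function(model, features) {
  if (model$n_neurons > 25L) stop("exact model moments require N <= 25")
  feats <- if (inherits(features, "feature_set")) features$features else features
  logw <- all_pattern_log_weights(model)
  p <- exp(logw - log_sum_exp(logw))
  keys <- 0:(2^model$n_neurons - 1)
  vapply(feats, function(f) {
    mask <- sum(bitwShiftL(1L, f - 1L))
    sum(p[bitwAnd(keys, mask) == mask])
  }, numeric(1))
}

#' Exact distribution of a model as an `empirical_dist`-like table
#'
#' @param model A `maxent_model` with N <= 25.
#' @param n_samples Effective sample size to attach (weights sum to this).
#' @return An `empirical_dist` whose counts are `n_samples * P(x)` over all
#'   2^N patterns.
#' @export
model_exact_distribution <- function(model, n_samples = 1e4) {
  if (model$n_neurons > 25L) stop("exact enumeration requires N <= 25")
  logw <- all_pattern_log_weights(model)
  p <- exp(logw - log_sum_exp(logw))
  keys <- 0:(2^model$n_neurons - 1)
  distribution_from_probs(key_to_pattern(keys, model$n_neurons), p, n_samples)
}
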