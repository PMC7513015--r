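# shared fixtures: everything is generated in code, nothing read from disk

# closed-form toy quantities at alpha = 1, beta = 1.2
toy_z <- function(alpha = 1, beta = 1.2) {
  1 + 3 * exp(-alpha) + 3 * exp(-2 * alpha + beta) + exp(-3 * alpha + 3 * beta)
}
toy_probs_by_count <- function(alpha = 1, beta = 1.2) {
  exp(c(0, -alpha, -2 * alpha + beta, -3 * alpha + 3 * beta)) / toy_z(alpha, beta)
}

# a reproducible random binary raster with heterogeneous rates
random_raster <- function(m, n, seed, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(n, 0.05, 0.6)
  spike_raster(matrix(rbinom(m * n, 1, rep(p, each = m)), m, n))
}

# canonical string form of a feature set, for set equality checks
feature_signature <- function(fs) {
  feats <- if (inherits(fs, "feature_set")) fs$features else fs
  sort(vapply(feats, function(f) paste(sort(f), collapse = ","), character(1)))
}

toy_feature_list <- function() {
  list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), c(1L, 2L, 3L))
}
toy_truth_theta <- c(-1, -1, -1, 1.2, 1.2, 1.2, 0)
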