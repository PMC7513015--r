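#' Reliable Interaction (RI) model
#'
#' The RI model is the pattern-frequency baseline: its features are the
#' supports of the "reliable" (high-frequency) non-silent spiking patterns,
#' its partition estimate is the inverse frequency of the silent state,
#' \eqn{Z_{RI} = \hat{P}(0\cdots0)^{-1}}, and its parameters are solved
#' algebraically so that every reliable pattern's predicted frequency equals
#' its empirical frequency exactly. The construction is essentially
#' instantaneous but does not produce a normalized distribution: predicted
#' frequencies over all 2^N patterns generally do not sum to 1, and
#' predictions for rare patterns can be incoherent (even exceeding 1).
#'
#' @name ri_model
NULL

new_ri_model <- function(n_neurons, features, theta, z_ri, p_min) {
  structure(list(n_neurons = as.integer(n_neurons), features = features,
                 theta = as.numeric(theta), z_ri = as.numeric(z_ri),
                 p_min = p_min),
            class = "ri_model")
}

#' @export
print.ri_model <- function(x, ...) {
  cat(sprintf("ri_model: %d neurons, %d features, Z_RI = %.4g (p_min = %g)\n",
              x$n_neurons, length(x$features), x$z_ri, x$p_min))
  invisible(x)
}

#' Identify reliable spiking patterns
#'
#' Patterns whose observed frequency is at least `p_min`; the silent pattern
#' is always included when observed (it anchors the partition estimate).
#'
#' @param dist An `empirical_dist`.
#' @param p_min Frequency threshold in (0, 1]; comparison is `>=`.
#' @return Integer vector of reliable pattern keys (sorted).
#' @export
identify_reliable_patterns <- function(dist, p_min) {
  if (!is.numeric(p_min) || p_min <= 0 || p_min > 1) {
    stop("p_min must lie in (0, 1]")
  }
  if (!(0L %in% dist$keys)) {
    stop("the silent pattern was never observed, so Z_RI = 1/P(silent) ",
         "is undefined; the RI model cannot be fitted to these data")
  }
  freq <- dist$counts / dist$n_samples
  keys <- dist$keys[freq >= p_min]
  sort(unique(c(0L, keys)))
}

#' Fit a Reliable Interaction model
#'
#' Sets \eqn{Z_{RI} = 1/\hat{P}(0\cdots0)}, takes the supports of the
#' non-silent reliable patterns as features, and solves the parameters
#' recursively in order of increasing support size:
#' \deqn{\theta_S = \log\big(Z_{RI}\, \hat{P}(x_S)\big) -
#'   \sum_{T \subsetneq S,\ T \in \mathrm{features}} \theta_T,}
#' where \eqn{x_S} is the pattern with support S. Sub-patterns of a reliable
#' pattern that are not themselves reliable contribute no term - this is what
#' makes RI feature sets non-downward-closed and produces spurious pure
#' higher-order models.
#'
#' @param dist An `empirical_dist` (observed or exact-weighted).
#' @param p_min Frequency threshold in (0, 1].
#' @return An `ri_model`.
#' @examples
#' d <- toy_exact_distribution()
#' fit_ri(d, 0.1)  # single triplet feature, theta = 0.6
#' @export
fit_ri <- function(dist, p_min) {
  keys <- identify_reliable_patterns(dist, p_min)
  z_ri <- 1 / pattern_frequency(dist, 0L)
  feat_keys <- keys[keys != 0L]
  if (length(feat_keys) == 0L) {
    return(new_ri_model(dist$n_neurons, list(), numeric(0), z_ri, p_min))
  }
  supports <- lapply(feat_keys, function(k) {
    which(bitwAnd(k, bitwShiftL(1L, seq_len(dist$n_neurons) - 1L)) != 0L)
  })
  # size-respecting order (ties broken by key) makes the recursion well-defined
  o <- order(lengths(supports), feat_keys)
  feat_keys <- feat_keys[o]
  supports <- supports[o]
  theta <- numeric(length(feat_keys))
  freqs <- pattern_frequency(dist, feat_keys)
  for (s in seq_along(feat_keys)) {
    ks <- feat_keys[s]
    sub <- which(bitwAnd(feat_keys[seq_len(s - 1L)], ks) ==
                   feat_keys[seq_len(s - 1L)])
    theta[s] <- log(z_ri * freqs[s]) - sum(theta[sub])
  }
  new_ri_model(dist$n_neurons, supports, theta, z_ri, p_min)
}

#' Predicted pattern frequency under an RI model
#'
#' \eqn{\hat{P}_{RI}(x) = \exp\{\sum_{S: S \subseteq \mathrm{supp}(x)}
#' \theta_S\}/Z_{RI}}. Deliberately not clamped: values can exceed 1 for rare
#' patterns, which is one of the diagnostic failure modes of the baseline.
#'
#' @param model An `ri_model`.
#' @param pattern A 0/1 vector or matrix of patterns (rows).
#' @return Nonnegative predicted frequencies (not probabilities; they need
#'   not sum to 1).
#' @export
ri_pattern_frequency <- function(model, pattern) {
  p <- check_patterns_arg(pattern, model$n_neurons)
  lw <- if (length(model$features) == 0L) numeric(nrow(p)) else
    drop(feature_activity(p, model$features) %*% model$theta)
  exp(lw) / model$z_ri
}

#' Total predicted mass of an RI model over all patterns
#'
#' Sums the predicted frequencies over all 2^N patterns (N <= 25). For a
#' normalized model this is 1; RI fits generally deviate from 1, which is the
#' concrete sense in which the model is not a probability distribution.
#'
#' @param model An `ri_model`.
#' @return Total predicted mass.
#' @export
ri_total_mass <- function(model) {
  if (model$n_neurons > 25L) stop("total mass requires N <= 25")
  proxy <- list(n_neurons = model$n_neurons, features = model$features,
                theta = model$theta)
  sum(exp(all_pattern_log_weights(proxy))) / model$z_ri
}
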