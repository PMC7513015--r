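#' Moment threshold from a relative-error bound
#'
#' Converts a maximum desired relative error in the sample moments into the
#' moment threshold that bounds its 95% confidence interval:
#' \deqn{p_{min} = \frac{1}{1 + M(\alpha/2)^2},}
#' where M is the number of samples. Moments at or above this threshold are
#' estimated by their sample frequency with relative error at most
#' `alpha_rel` at the 95% level. The bound is strictly decreasing in both M
#' and `alpha_rel`: more data, or a looser error demand, admits smaller
#' moments.
#'
#' @param n_samples Number of time bins M (>= 1).
#' @param alpha_rel Maximum desired relative error (> 0). Unrelated to any
#'   interaction-strength parameter; it is purely a sampling-error bound.
#' @return The moment threshold p_min in (0, 1].
#' @examples
#' threshold_from_error(10000, 1)   # 1/2501
#' threshold_from_error(4, 2)       # 1/5
#' @export
threshold_from_error <- function(n_samples, alpha_rel) {
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("n_samples must be a positive number of samples")
  }
  if (!is.numeric(alpha_rel) || alpha_rel <= 0) {
    stop("alpha_rel must be > 0")
  }
  1 / (1 + n_samples * (alpha_rel / 2)^2)
}

#' Identify the reliable moments of a raster
#'
#' Finds every neuron subset whose uncentered empirical moment is at least
#' `p_min`. Because the moment of a set is bounded by the moment of each of
#' its subsets, the result is downward-closed, and the search can proceed
#' level-wise (Apriori-style): order-k candidates are formed only from pairs
#' of selected order-(k-1) features sharing a common (k-2)-prefix, and kept
#' only if all their (k-1)-subsets were selected. The search stops at the
#' first empty level.
#'
#' @param raster A `spike_raster` or binary matrix.
#' @param p_min Moment threshold in (0, 1]. Comparison is `>=` (ties
#'   included).
#' @param max_order Optional cap on feature order (default unlimited); a
#'   guard for pathologically dense rasters.
#' @return A `feature_set`, ordered by increasing order then lexicographically.
#'   May be empty.
#' @examples
#' r <- spike_raster(matrix(1L, 10, 3))
#' length(identify_reliable_moments(r, 0.5))  # all 7 subsets
#' @export
identify_reliable_moments <- function(raster, p_min, max_order = Inf) {
  if (!is.numeric(p_min) || p_min <= 0 || p_min > 1) {
    stop("p_min must lie in (0, 1]")
  }
  x <- as_raster_matrix(raster)
  m <- nrow(x)
  n <- ncol(x)
  storage.mode(x) <- "logical"

  selected <- list()
  # level 1: single neurons with firing probability >= p_min
  level_feats <- as.list(which(colMeans(x) >= p_min))
  level_act <- lapply(level_feats, function(i) x[, i])
  selected <- level_feats

  k <- 1L
  while (length(level_feats) > 1L && k < max_order && k < n) {
    sel_keys <- vapply(level_feats, function(f) sum(2^(f - 1L)), numeric(1))
    cand_feats <- list()
    cand_act <- list()
    # join survivors sharing the first k-1 indices (lexicographic prefix join)
    prefixes <- vapply(level_feats, function(f) {
      paste(f[-length(f)], collapse = ",")
    }, character(1))
    for (grp in split(seq_along(level_feats), prefixes)) {
      if (length(grp) < 2L) next
      lasts <- vapply(level_feats[grp], function(f) f[length(f)], integer(1))
      o <- order(lasts)
      grp <- grp[o]
      lasts <- lasts[o]
      for (a in seq_len(length(grp) - 1L)) {
        for (b in (a + 1L):length(grp)) {
          cand <- c(level_feats[[grp[a]]], lasts[b])
          # all (k)-subsets of the (k+1)-candidate must be selected
          ok <- all(vapply(seq_along(cand), function(drop_i) {
            sum(2^(cand[-drop_i] - 1L)) %in% sel_keys
          }, logical(1)))
          if (!ok) next
          act <- level_act[[grp[a]]] & level_act[[grp[b]]]
          if (sum(act) / m >= p_min) {
            cand_feats[[length(cand_feats) + 1L]] <- cand
            cand_act[[length(cand_act) + 1L]] <- act
          }
        }
      }
    }
    if (length(cand_feats) == 0L) break
    selected <- c(selected, cand_feats)
    level_feats <- cand_feats
    level_act <- cand_act
    k <- k + 1L
  }
  feature_set(selected, n)
}

#' Test whether a feature set is downward-closed
#'
#' A feature set is downward-closed when every nonempty proper subset of every
#' member is itself a member. Moment-thresholded (RM) feature sets always have
#' this property; pattern-frequency (RI) feature sets generally do not.
#'
#' @param fs A `feature_set` or list of index vectors.
#' @return TRUE or FALSE.
#' @examples
#' is_downward_closed(feature_set(list(1, 2, c(1, 2)), 2))   # TRUE
#' is_downward_closed(feature_set(list(1, c(1, 2)), 2))      # FALSE
#' @export
is_downward_closed <- function(fs) {
  feats <- if (inherits(fs, "feature_set")) fs$features else
    lapply(fs, function(f) sort(as.integer(f)))
  if (length(feats) == 0L) return(TRUE)
  keys <- feature_keys_internal(feats)
  for (f in feats) {
    if (length(f) == 1L) next
    for (drop_i in seq_along(f)) {
      if (!(sum(2^(f[-drop_i] - 1L)) %in% keys)) return(FALSE)
    }
  }
  TRUE
}

#' Brute-force reliable-moment scan (oracle)
#'
#' Enumerates all 2^N - 1 nonempty neuron subsets and keeps those with
#' empirical moment >= `p_min`. Exponential in N; intended as a correctness
#' oracle for [identify_reliable_moments()] on small populations.
#'
#' @inheritParams identify_reliable_moments
#' @return A `feature_set`.
#' @export
reliable_moments_bruteforce <- function(raster, p_min, max_order = Inf) {
  x <- as_raster_matrix(raster)
  n <- ncol(x)
  if (n > 15L) stop("brute-force scan limited to N <= 15")
  feats <- list()
  for (key in seq_len(2^n - 1)) {
    f <- which(bitwAnd(key, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(f) > max_order) next
    if (mean(rowSums(x[, f, drop = FALSE]) == length(f)) >= p_min) {
      feats[[length(feats) + 1L]] <- f
    }
  }
  feature_set(feats, n)
}

# canonical ordering used when comparing feature sets: by order, then by key
sort_feature_set <- function(fs) {
  o <- order(feature_orders(fs), feature_keys_internal(fs$features))
  feature_set(fs$features[o], fs$n_neurons)
}
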