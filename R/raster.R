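#' Spike raster container
#'
#' A spike raster is an M x N binary matrix: rows are time bins, columns are
#' neurons, and entry (t, i) is 1 if neuron i spiked in bin t. The bin width
#' (in seconds) travels with the matrix so that per-bin spike probabilities
#' can be converted to firing rates in Hz.
#'
#' @param data Numeric or integer matrix whose entries are all exactly 0 or 1.
#' @param bin_width_s Width of one time bin in seconds (default 0.02, i.e.
#'   20 ms, the conventional bin for cortical population rasters).
#' @return An object of class `spike_raster`: the integer matrix with a
#'   `bin_width_s` attribute.
#' @examples
#' r <- spike_raster(matrix(c(1, 0, 0, 1, 1, 1), nrow = 2))
#' n_neurons(r)
#' @export
spike_raster <- function(data, bin_width_s = 0.02) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (nrow(data) < 1L || ncol(data) < 1L) {
    stop("spike raster must have at least one time bin and one neuron")
  }
  bad <- which(!(data == 0 | data == 1))
  if (length(bad) > 0L) {
    # strict binary check: report the first offending cell, no coercion
    i <- ((bad[1L] - 1L) %% nrow(data)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(data)) + 1L
    stop(sprintf("non-binary entry %s at row %d, column %d",
                 format(data[bad[1L]]), i, j))
  }
  if (!is.numeric(bin_width_s) || length(bin_width_s) != 1L || bin_width_s <= 0) {
    stop("bin_width_s must be a single positive number")
  }
  storage.mode(data) <- "integer"
  structure(data, bin_width_s = as.numeric(bin_width_s), class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d bins x %d neurons, bin width %g s\n",
              nrow(x), ncol(x), attr(x, "bin_width_s")))
  cat(sprintf("mean rate %.3g spikes/bin (%.3g Hz)\n",
              mean(x), mean(x) / attr(x, "bin_width_s")))
  invisible(x)
}

#' Number of neurons in a raster, distribution, or model
#'
#' @param x A `spike_raster`, `empirical_dist`, `maxent_model` or `ri_model`.
#' @return Integer count of neurons N.
#' @export
n_neurons <- function(x) {
  if (inherits(x, "spike_raster")) return(ncol(x))
  if (!is.null(x$n_neurons)) return(x$n_neurons)
  stop("cannot determine number of neurons for this object")
}

as_raster_matrix <- function(raster) {
  if (inherits(raster, "spike_raster")) return(unclass(raster))
  if (is.matrix(raster)) {
    bad <- !(raster == 0 | raster == 1)
    if (any(bad)) stop("raster matrix contains non-binary entries")
    storage.mode(raster) <- "integer"
    return(raster)
  }
  stop("expected a spike_raster or a binary matrix")
}

#' Pattern keys for binary spike patterns
#'
#' Encodes each row of a binary matrix as an integer key with neuron 1 in the
#' least-significant bit. Keys are exact for N <= 25, the same limit as the
#' brute-force partition function.
#'
#' @param patterns Binary matrix (rows = patterns) or a single 0/1 vector.
#' @return Integer vector of keys.
#' @export
pattern_key <- function(patterns) {
  if (is.vector(patterns)) patterns <- matrix(patterns, nrow = 1L)
  n <- ncol(patterns)
  if (n > 25L) stop("pattern keys support at most 25 neurons")
  as.integer(patterns %*% 2^(seq_len(n) - 1L))
}

#' Decode integer pattern keys back to binary patterns
#'
#' @param keys Integer vector of pattern keys (neuron 1 = least-significant bit).
#' @param n_neurons Number of neurons N.
#' @return Integer matrix, one row per key.
#' @export
key_to_pattern <- function(keys, n_neurons) {
  m <- matrix(0L, nrow = length(keys), ncol = n_neurons)
  for (j in seq_len(n_neurons)) {
    m[, j] <- bitwAnd(as.integer(keys), bitwShiftL(1L, j - 1L)) != 0L
  }
  storage.mode(m) <- "integer"
  m
}

#' Empirical distribution of spiking patterns
#'
#' Tabulates the distinct spiking patterns of a raster with their counts.
#' Weighted variants (non-integer counts) are allowed so that an exact model
#' distribution can be passed anywhere an empirical one is expected.
#'
#' @param raster A `spike_raster` (or binary matrix).
#' @return An object of class `empirical_dist` with elements
#'   `patterns` (unique patterns, one per row), `keys` (integer keys),
#'   `counts`, `n_samples` (sum of counts) and `n_neurons`.
#' @examples
#' d <- empirical_distribution(spike_raster(rbind(c(0,0,0), c(0,0,0), c(1,1,1))))
#' d$counts
#' @export
empirical_distribution <- function(raster) {
  x <- as_raster_matrix(raster)
  keys <- pattern_key(x)
  tab <- tabulate(match(keys, sort(unique(keys))), nbins = length(unique(keys)))
  ukeys <- sort(unique(keys))
  new_empirical_dist(key_to_pattern(ukeys, ncol(x)), ukeys, as.numeric(tab),
                     ncol(x))
}

new_empirical_dist <- function(patterns, keys, counts, n_neurons) {
  stopifnot(length(keys) == length(counts), nrow(patterns) == length(keys))
  structure(list(patterns = patterns, keys = as.integer(keys),
                 counts = as.numeric(counts), n_samples = sum(counts),
                 n_neurons = as.integer(n_neurons)),
            class = "empirical_dist")
}

#' Build a distribution object from explicit pattern probabilities
#'
#' Used to feed an exactly known distribution (e.g. the closed-form toy model)
#' into fitting routines as if it were data with effective sample size
#' `n_samples`.
#'
#' @param patterns Binary matrix of distinct patterns, one per row.
#' @param probs Probabilities (or weights) per pattern; must sum to a positive
#'   number and are rescaled to sum to `n_samples`.
#' @param n_samples Effective number of samples M the weights represent.
#' @return An `empirical_dist`.
#' @export
distribution_from_probs <- function(patterns, probs, n_samples = 1e4) {
  if (any(probs < 0) || sum(probs) <= 0) stop("probabilities must be nonnegative and not all zero")
  keys <- pattern_key(patterns)
  if (anyDuplicated(keys)) stop("duplicate patterns")
  o <- order(keys)
  new_empirical_dist(patterns[o, , drop = FALSE], keys[o],
                     probs[o] / sum(probs) * n_samples, ncol(patterns))
}

#' @export
print.empirical_dist <- function(x, ...) {
  cat(sprintf("empirical_dist: %d distinct patterns, %g samples, %d neurons\n",
              length(x$keys), x$n_samples, x$n_neurons))
  invisible(x)
}

#' Pattern frequency lookup
#'
#' @param dist An `empirical_dist`.
#' @param pattern A 0/1 vector of length N, a binary matrix of patterns
#'   (rows), or a vector of integer keys. A plain vector is read as a single
#'   pattern only when it has exactly N entries, all 0 or 1; anything else is
#'   treated as keys.
#' @return Frequencies count/M (0 for unobserved patterns).
#' @export
pattern_frequency <- function(dist, pattern) {
  keys <- if (is.matrix(pattern)) {
    pattern_key(pattern)
  } else if (length(pattern) == dist$n_neurons && all(pattern %in% c(0, 1))) {
    pattern_key(pattern)
  } else {
    as.integer(pattern)
  }
  idx <- match(keys, dist$keys)
  out <- ifelse(is.na(idx), 0, dist$counts[idx] / dist$n_samples)
  as.numeric(out)
}
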