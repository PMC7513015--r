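#' Dissimilarity between empirical and model pattern frequencies
#'
#' The weighted mean absolute base-2 log ratio
#' \deqn{d(P, Q) = \sum_{x \in D} P(x)\,\big|\log_2 P(x)/Q(x)\big|,}
#' over a domain D of patterns (by default every pattern observed in the
#' reference distribution, including those seen only once). Unlike the
#' Kullback-Leibler divergence it remains meaningful when Q is an
#' unnormalized frequency model such as an RI fit.
#'
#' @param p_ref The reference P: an `empirical_dist` (empirical frequencies),
#'   or a `maxent_model` with `log_z` set / a pattern-to-probability function
#'   (exact ground-truth reference, in which case `domain` must be given).
#' @param q_model A function mapping a pattern matrix (rows) to predicted
#'   frequencies, or a fitted `maxent_model` (uses [pattern_probability()])
#'   or `ri_model` (uses [ri_pattern_frequency()]).
#' @param domain Optional matrix of patterns or integer keys defining D;
#'   default: all patterns observed in `p_ref`. Patterns with P(x) = 0 drop
#'   out of the sum.
#' @return Nonnegative dissimilarity; 0 iff P = Q on D.
#' @export
dissimilarity <- function(p_ref, q_model, domain = NULL) {
  is_dist <- inherits(p_ref, "empirical_dist")
  if (is.null(domain)) {
    if (!is_dist) stop("an explicit domain is required unless p_ref is an empirical_dist")
    pats <- p_ref$patterns
  } else if (is.matrix(domain)) {
    pats <- domain
  } else {
    if (is.null(p_ref$n_neurons)) {
      stop("pass domain as a pattern matrix when p_ref is a function")
    }
    pats <- key_to_pattern(as.integer(domain), p_ref$n_neurons)
  }
  if (nrow(pats) == 0L) return(0)
  p <- if (is_dist) pattern_frequency(p_ref, pattern_key(pats)) else
    model_frequencies(p_ref, pats)
  log2q <- model_log2_frequencies(q_model, pats)
  live <- p > 0
  if (any(log2q[live] == -Inf | is.nan(log2q[live]))) {
    k <- pattern_key(pats)[live][which(!(log2q[live] > -Inf))[1L]]
    stop(sprintf(
      "model frequency is not positive for observed pattern with key %d", k))
  }
  sum(p[live] * abs(log2(p[live]) - log2q[live]))
}

# base-2 log frequencies, staying in log space for the log-linear model
# classes (their probabilities are positive by construction even when exp()
# would underflow to 0)
model_log2_frequencies <- function(q_model, patterns) {
  if (inherits(q_model, "maxent_model")) {
    if (is.null(q_model$log_z)) {
      stop("model has no log_z; compute a partition estimate first")
    }
    return((log_weight(q_model, patterns) - q_model$log_z) / log(2))
  }
  if (inherits(q_model, "ri_model")) {
    p <- check_patterns_arg(patterns, q_model$n_neurons)
    lw <- if (length(q_model$features) == 0L) numeric(nrow(p)) else
      drop(feature_activity(p, q_model$features) %*% q_model$theta)
    return((lw - log(q_model$z_ri)) / log(2))
  }
  suppressWarnings(log2(model_frequencies(q_model, patterns)))
}

model_frequencies <- function(q_model, patterns) {
  if (is.function(q_model)) return(q_model(patterns))
  if (inherits(q_model, "maxent_model")) {
    return(pattern_probability(q_model, patterns))
  }
  if (inherits(q_model, "ri_model")) {
    return(ri_pattern_frequency(q_model, patterns))
  }
  stop("q_model must be a function, maxent_model, or ri_model")
}

#' Split test patterns into old and new
#'
#' "Old" patterns occurred in both training and test data; "new" patterns
#' occur only in the test data. The number of new patterns grows quickly with
#' population size at fixed recording length, which is where normalized
#' models earn their keep.
#'
#' @param train,test `empirical_dist` objects over the same N neurons.
#' @return List with integer key vectors `old` and `new` (partitioning the
#'   test support).
#' @export
split_old_new <- function(train, test) {
  if (train$n_neurons != test$n_neurons) stop("neuron count mismatch")
  is_old <- test$keys %in% train$keys
  list(old = test$keys[is_old], new = test$keys[!is_old])
}

#' Magnitude statistics of higher-order interaction parameters
#'
#' Count, mean and SD of |theta| over features of order >= `min_order`
#' (default 3). When the data truly come from a pairwise model, these
#' parameters should all be zero; their fitted magnitudes measure how much
#' spurious higher-order structure a fitting procedure infers.
#'
#' @param model A `maxent_model` or `ri_model`.
#' @param min_order Smallest order counted as "higher-order" (default 3).
#' @return List with `count`, `mean_abs`, `sd_abs` (0, 0, 0 when no such
#'   features exist; `sd_abs` is 0 for a single feature).
#' @export
hoi_magnitude_stats <- function(model, min_order = 3L) {
  ord <- lengths(model$features)
  sel <- which(ord >= min_order)
  if (length(sel) == 0L) return(list(count = 0L, mean_abs = 0, sd_abs = 0))
  a <- abs(model$theta[sel])
  list(count = length(sel), mean_abs = mean(a),
       sd_abs = if (length(a) > 1L) stats::sd(a) else 0)
}

#' Pairwise Pearson correlations of a spike raster
#'
#' Pearson correlation of the per-bin binary indicators, the standard
#' correlation measure for binned spike data. Neurons with zero variance
#' (never or always spiking) yield NA entries.
#'
#' @param raster A `spike_raster` or binary matrix.
#' @return N x N symmetric matrix with unit diagonal.
#' @export
pearson_correlations <- function(raster) {
  x <- as_raster_matrix(raster)
  storage.mode(x) <- "numeric"
  v <- apply(x, 2L, stats::var)
  suppressWarnings(r <- stats::cor(x))
  r[v == 0, ] <- NA_real_
  r[, v == 0] <- NA_real_
  diag(r) <- ifelse(v == 0, NA_real_, 1)
  r
}

#' Run an RM vs RI comparison experiment
#'
#' For each ground-truth population, draws a training and a test raster,
#' fits RM models across a grid of moment thresholds and RI models across a
#' grid of pattern-frequency thresholds, and tabulates per fit: feature
#' counts by order, higher-order parameter magnitudes, dissimilarity to the
#' test distribution on all/old/new patterns, whether any predicted
#' frequency of a test singleton pattern exceeds 1, and the fit wall-time.
#'
#' @param ground_truth_class `"pairwise"` (random pairwise maximum entropy
#'   populations) or `"dg"` (Dichotomized Gaussian populations with
#'   cortical-like rates and correlations).
#' @param n_neurons Population size (default 20).
#' @param n_populations Number of ground-truth populations (default 5).
#' @param rm_thresholds Moment-threshold grid for RM (default 5 log-spaced
#'   values in \[0.001, 0.05\]).
#' @param ri_thresholds Frequency-threshold grid for RI (default 5 log-spaced
#'   values in \[1e-5, 5e-3\]).
#' @param n_train,n_test Training and test sample counts (default 10000 each,
#'   i.e. 200 s of 20 ms bins).
#' @param seed Base seed; population s uses seeds derived from `seed + s`.
#' @param fit A [fit_config()] for the RM fits.
#' @param z_method Partition method for RM models (default Good-Turing, the
#'   estimator used at scale).
#' @param max_order Optional cap on RM feature order.
#' @return A data.frame with one row per (population, model class, threshold);
#'   failed cells (e.g. an RI fit with no observed silent state) are recorded
#'   with `error` set and metric columns NA.
#' @export
run_comparison_experiment <- function(ground_truth_class = c("pairwise", "dg"),
                                      n_neurons = 20L, n_populations = 5L,
                                      rm_thresholds = exp(seq(log(0.05),
                                        log(0.001), length.out = 5)),
                                      ri_thresholds = exp(seq(log(5e-3),
                                        log(1e-5), length.out = 5)),
                                      n_train = 10000L, n_test = 10000L,
                                      seed = 1L, fit = fit_config(),
                                      z_method = "good_turing",
                                      max_order = Inf) {
  ground_truth_class <- match.arg(ground_truth_class)
  rows <- list()
  for (pop in seq_len(n_populations)) {
    pop_seed <- as.integer(seed) + pop
    if (ground_truth_class == "pairwise") {
      gt <- sample_ground_truth_pairwise(n_neurons, seed = pop_seed)
      train <- gibbs_sample(gt, n_train, seed = pop_seed * 1000L + 1L)
      test <- gibbs_sample(gt, n_test, seed = pop_seed * 1000L + 2L)
    } else {
      tg <- sample_cortical_targets(n_neurons, seed = pop_seed)
      spec <- dg_calibrate(tg$rates, tg$corr)
      train <- dg_sample(spec, n_train, seed = pop_seed * 1000L + 1L)
      test <- dg_sample(spec, n_test, seed = pop_seed * 1000L + 2L)
    }
    train_dist <- empirical_distribution(train)
    test_dist <- empirical_distribution(test)
    split <- split_old_new(train_dist, test_dist)
    singles <- test_dist$keys[test_dist$counts == 1]

    eval_cell <- function(model_class, threshold, fitter) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(fitter(), error = function(e) e)
      elapsed <- proc.time()[["elapsed"]] - t0
      base <- data.frame(population = pop, class = ground_truth_class,
                         model = model_class, threshold = threshold,
                         fit_seconds = elapsed, stringsAsFactors = FALSE)
      if (inherits(res, "error")) {
        return(cbind(base, data.frame(
          n_features = NA_integer_, n_hoi = NA_integer_,
          hoi_mean_abs = NA_real_, hoi_sd_abs = NA_real_,
          d_all = NA_real_, d_old = NA_real_, d_new = NA_real_,
          max_singleton_freq = NA_real_, error = conditionMessage(res))))
      }
      hs <- hoi_magnitude_stats(res)
      d_for <- function(keys) {
        if (length(keys) == 0L) return(NA_real_)
        tryCatch(dissimilarity(test_dist, res,
                               key_to_pattern(keys, n_neurons)),
                 error = function(e) NA_real_)
      }
      msf <- if (length(singles) == 0L) NA_real_ else
        max(model_frequencies(res, key_to_pattern(singles, n_neurons)))
      cbind(base, data.frame(
        n_features = length(res$features), n_hoi = hs$count,
        hoi_mean_abs = hs$mean_abs, hoi_sd_abs = hs$sd_abs,
        d_all = d_for(test_dist$keys), d_old = d_for(split$old),
        d_new = d_for(split$new), max_singleton_freq = msf,
        error = NA_character_))
    }

    for (th in rm_thresholds) {
      rows[[length(rows) + 1L]] <- eval_cell("rm", th, function() {
        fit_rm(train, p_min = th, config = fit, z_method = z_method,
               max_order = max_order)
      })
    }
    for (th in ri_thresholds) {
      rows[[length(rows) + 1L]] <- eval_cell("ri", th, function() {
        fit_ri(train_dist, th)
      })
    }
  }
  do.call(rbind, rows)
}
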