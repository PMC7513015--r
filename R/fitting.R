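#' Fit configuration
#'
#' @param method `"mpf"` (Minimum Probability Flow, fast, default) or
#'   `"exact_ml"` (maximum likelihood with exact enumeration of model
#'   moments; the convex reference, N <= 20).
#' @param tol Gradient-norm convergence tolerance (default 1e-6).
#' @param max_iterations Maximum optimizer iterations (default 500).
#' @param l2_penalty Ridge penalty on theta (default 0).
#' @param seed Integer seed recorded with the fit (the optimizers themselves
#'   are deterministic).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(method = c("mpf", "exact_ml"), tol = 1e-6,
                       max_iterations = 500L, l2_penalty = 0, seed = 1L) {
  method <- match.arg(method)
  if (tol <= 0) stop("tol must be > 0")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (l2_penalty < 0) stop("l2_penalty must be >= 0")
  structure(list(method = method, tol = tol,
                 max_iterations = as.integer(max_iterations),
                 l2_penalty = l2_penalty, seed = as.integer(seed)),
            class = "fit_config")
}

# Precomputed MPF design: one tall sparse matrix A over rows (site i, data
# pattern p) and columns (features), with entry s_pi * prod_{j in F \ i} x_j
# for features F containing i, where s_pi = +1 if x_i = 0 (the flip switches
# the feature on) and -1 otherwise. A %*% theta is then the vector of
# log-weight differences to every single-bit-flip neighbour of every data
# pattern. Sparse storage keeps large fits (thousands of features) cheap:
# higher-order columns are nonzero only where the feature's other members
# co-spike.
mpf_design <- function(dist, features) {
  feats <- if (inherits(features, "feature_set")) features$features else features
  u <- matrix(as.numeric(dist$patterns), nrow = nrow(dist$patterns))
  n <- dist$n_neurons
  m <- nrow(u)
  # activity cache keyed by feature bitmask; for downward-closed sets every
  # "other members" subset is itself a feature, so each activity is one
  # logical AND on top of an already-cached subset
  cache <- new.env(parent = emptyenv())
  activity_of <- function(f) {
    if (length(f) == 0L) return(rep(TRUE, m))
    key <- paste0("k", sum(2^(f - 1L)))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (length(f) == 1L) u[, f] == 1 else
      activity_of(f[-length(f)]) & (u[, f[length(f)]] == 1)
    cache[[key]] <- val
    val
  }
  ii <- jj <- vector("list", 0L)
  xx <- vector("list", 0L)
  idx <- 0L
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    for (i in f) {
      rows <- which(activity_of(setdiff(f, i)))
      if (length(rows) == 0L) next
      idx <- idx + 1L
      ii[[idx]] <- (i - 1L) * m + rows          # row block for site i
      jj[[idx]] <- rep.int(k, length(rows))
      xx[[idx]] <- 1 - 2 * u[rows, i]           # sign s_pi
    }
  }
  a <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n * m, length(feats)))
  list(design = a,
       weights = rep.int(dist$counts / dist$n_samples, n),
       n_features = length(feats), n_sites = n)
}

#' Minimum Probability Flow objective and gradient
#'
#' MPF sidesteps the partition function by penalizing probability flow from
#' the data states to their single-bit-flip neighbours under the model:
#' \deqn{K(\theta) = \frac{1}{M} \sum_{x \in \mathrm{data}}
#'   \sum_{x' \in \mathrm{nbr}(x)}
#'   \exp\left\{\tfrac{1}{2}\big(\log w(x') - \log w(x)\big)\right\},}
#' where nbr(x) are the N patterns one bit-flip away. K >= 0, and K is
#' minimized (stationary) at the data-generating parameters when the
#' empirical distribution lies in the model class.
#'
#' @param theta Parameter vector, one entry per feature.
#' @param features A `feature_set` or list of index vectors.
#' @param dist An `empirical_dist` over the data patterns.
#' @param design Optional precomputed design from repeated evaluation at the
#'   same (features, dist); computed on the fly if missing.
#' @param l2_penalty Optional ridge penalty added as
#'   `l2_penalty * sum(theta^2)`.
#' @return List with elements `value` (K) and `gradient` (exact analytic
#'   gradient dK/dtheta).
#' @export
mpf_objective <- function(theta, features, dist, design = NULL,
                          l2_penalty = 0) {
  if (any(!is.finite(theta))) stop("theta must be finite")
  if (is.null(design)) design <- mpf_design(dist, features)
  if (length(theta) != design$n_features) {
    stop("theta length does not match the number of features")
  }
  w <- design$weights
  d <- as.numeric(design$design %*% theta)
  e <- exp(0.5 * d)
  value <- sum(w * e)
  grad <- 0.5 * as.numeric(Matrix::crossprod(design$design, w * e))
  if (l2_penalty > 0) {
    value <- value + l2_penalty * sum(theta^2)
    grad <- grad + 2 * l2_penalty * theta
  }
  list(value = value, gradient = grad)
}

exact_ml_newton_polish <- function(theta, n, feats, dist, l2_penalty,
                                   steps = 8L, tol = 1e-13) {
  if (2^n * length(feats) > 2e7) return(theta)  # dense design too large
  dm <- distribution_moments(dist, feats)
  phi <- feature_activity(key_to_pattern(0:(2^n - 1), n), feats)
  for (it in seq_len(steps)) {
    m <- maxent_model(n, feats, theta)
    logw <- all_pattern_log_weights(m)
    p <- exp(logw - log_sum_exp(logw))
    mm <- drop(crossprod(phi, p))
    g <- mm - dm + 2 * l2_penalty * theta
    if (max(abs(g)) < tol) break
    h <- crossprod(phi, phi * p) - tcrossprod(mm)
    if (l2_penalty > 0) h <- h + diag(2 * l2_penalty, length(theta))
    step <- tryCatch(solve(h + diag(1e-12, nrow(h)), g),
                     error = function(e) NULL)
    if (is.null(step)) break
    theta <- theta - step
  }
  theta
}

# negative mean log-likelihood and gradient for the exact-ML route
# (gradient = model moments - data moments; convex in theta)
exact_ml_objective <- function(theta, model_template, dist, data_moments,
                               l2_penalty = 0) {
  m <- model_template
  m$theta <- theta
  logz <- exact_log_partition(m)
  nll <- logz - sum(data_moments * theta)
  g <- model_moments_exact(m, m$features) - data_moments
  if (l2_penalty > 0) {
    nll <- nll + l2_penalty * sum(theta^2)
    g <- g + 2 * l2_penalty * theta
  }
  list(value = nll, gradient = g)
}

#' Fit interaction parameters to a distribution of spiking patterns
#'
#' Estimates one interaction parameter per feature, either by Minimum
#' Probability Flow (default; no partition function needed, scales to the
#' population sizes used in practice) or by exact maximum likelihood
#' (enumerates all 2^N patterns per iteration; the convex reference whose
#' optimum matches the data moments of every fitted feature).
#'
#' The returned model has `z_method = "none"`: normalization is a separate
#' step ([exact_log_partition()], [good_turing_log_partition()],
#' [gibbs_silent_state_log_partition()]).
#'
#' @param dist An `empirical_dist` (observed or exact-weighted patterns).
#' @param features A nonempty `feature_set` or list of index vectors.
#' @param config A [fit_config()].
#' @return A `maxent_model` with attributes `converged` (logical),
#'   `grad_norm`, and `iterations`.
#' @export
fit_parameters <- function(dist, features, config = fit_config()) {
  feats <- if (inherits(features, "feature_set")) features$features else features
  if (length(feats) == 0L) stop("feature set is empty")
  if (dist$n_samples <= 0) stop("distribution is empty")
  n <- dist$n_neurons
  theta0 <- numeric(length(feats))

  if (config$method == "exact_ml") {
    if (n > 20L) stop("exact_ml requires N <= 20; use method = 'mpf'")
    template <- maxent_model(n, feats, theta0)
    dm <- distribution_moments(dist, feats)
    if (any(dm <= 0) || any(dm >= 1)) {
      stop("exact_ml requires data moments strictly inside (0, 1) ",
           "for all fitted features")
    }
    fn <- function(th) exact_ml_objective(th, template, dist, dm,
                                          config$l2_penalty)$value
    gr <- function(th) exact_ml_objective(th, template, dist, dm,
                                          config$l2_penalty)$gradient
  } else {
    design <- mpf_design(dist, feats)
    fn <- function(th) mpf_objective(th, feats, dist, design,
                                     config$l2_penalty)$value
    gr <- function(th) mpf_objective(th, feats, dist, design,
                                     config$l2_penalty)$gradient
  }

  # dense BFGS is exact-Hessian-quality for small parameter counts; its
  # O(p^2) update dominates for the thousands of features a low threshold can
  # select, where limited-memory L-BFGS-B wins
  opt <- if (length(theta0) <= 200L) {
    stats::optim(theta0, fn, gr, method = "BFGS",
                 control = list(maxit = config$max_iterations,
                                reltol = 1e-14))
  } else {
    stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = config$max_iterations,
                                factr = 10, pgtol = 0, lmm = 20))
  }
  if (config$method == "exact_ml") {
    # Newton polish: the exact-ML problem is convex with Hessian equal to
    # the feature covariance under the model, so a few Newton steps from the
    # BFGS optimum drive the moment mismatch to machine precision
    opt$par <- exact_ml_newton_polish(opt$par, n, feats, dist,
                                      config$l2_penalty)
  }
  gnorm <- sqrt(sum(gr(opt$par)^2))
  converged <- gnorm < config$tol
  if (!converged) {
    warning(sprintf(
      "optimizer stopped with gradient norm %.3g (tolerance %.3g); %s",
      gnorm, config$tol, "returning best iterate"))
  }
  model <- maxent_model(n, feats, opt$par)
  attr(model, "converged") <- converged
  attr(model, "grad_norm") <- gnorm
  attr(model, "iterations") <- opt$counts[["function"]]
  attr(model, "fit_method") <- config$method
  model
}

#' Good-Turing estimate of the log partition function
#'
#' The summed unnormalized weights of the observed patterns estimate
#' \eqn{Z \cdot C}, where C is the probability mass the model places on the
#' observed support. C is estimated by the Good-Turing coverage
#' \eqn{\hat{C} = 1 - N_1/M} (N_1 = number of patterns seen exactly once), so
#' \deqn{\log \hat{Z} = \log \sum_{\mathrm{unique}\ u} w(u) - \log \hat{C}.}
#'
#' @param model A fitted `maxent_model`.
#' @param dist The `empirical_dist` of the training data.
#' @param coverage_floor Lower clamp for the coverage estimate (default 1e-6);
#'   hitting it triggers a warning, since almost-all-singleton data carries no
#'   information about the unobserved mass.
#' @return log of the estimated partition function.
#' @export
good_turing_log_partition <- function(model, dist, coverage_floor = 1e-6) {
  if (dist$n_samples <= 0) stop("distribution is empty")
  logw <- log_weight(model, dist$patterns)
  n1 <- sum(dist$counts == 1)
  coverage <- 1 - n1 / dist$n_samples
  if (coverage <= coverage_floor) {
    warning(sprintf(
      "Good-Turing coverage estimate %.3g at or below floor %.3g; %s",
      coverage, coverage_floor,
      "partition estimate is unreliable (nearly all patterns are singletons)"))
    coverage <- coverage_floor
  }
  log_sum_exp(logw) - log(coverage)
}

#' Fit a Reliable Moment model to a spike raster
#'
#' The full pipeline: (1) select all features whose uncentered empirical
#' moments are at least `p_min` (downward-closed by the moment hierarchy);
#' (2) fit their interaction parameters; (3) attach a partition function so
#' the model is a normalized distribution.
#'
#' @param raster A `spike_raster` or binary matrix.
#' @param p_min Moment threshold; alternatively give `alpha_rel` and the
#'   threshold is derived from the 95% relative-error bound
#'   ([threshold_from_error()]). Exactly one of the two must be supplied.
#' @param alpha_rel Maximum desired relative error of the retained moments.
#' @param config A [fit_config()].
#' @param z_method `"auto"` (exact for N <= 20, Good-Turing beyond),
#'   `"exact"`, `"good_turing"`, `"gibbs_silent_state"`, or `"none"`.
#' @param max_order Optional cap on feature order passed to selection.
#' @param ... Passed to the partition estimator (e.g. `n_samples`, `seed` for
#'   the Gibbs route).
#' @return A normalized `maxent_model` (unless `z_method = "none"`), with the
#'   selection threshold in attribute `p_min`.
#' @export
fit_rm <- function(raster, p_min = NULL, alpha_rel = NULL,
                   config = fit_config(), z_method = c("auto", "exact",
                   "good_turing", "gibbs_silent_state", "none"),
                   max_order = Inf, ...) {
  z_method <- match.arg(z_method)
  if (is.null(p_min) == is.null(alpha_rel)) {
    stop("supply exactly one of p_min or alpha_rel")
  }
  x <- as_raster_matrix(raster)
  if (is.null(p_min)) p_min <- threshold_from_error(nrow(x), alpha_rel)
  if (p_min > 1) stop("p_min must be <= 1")
  fs <- identify_reliable_moments(x, p_min, max_order = max_order)
  if (length(fs$features) == 0L) {
    stop(sprintf(
      "no moment reaches p_min = %g; the largest firing rate is %g, so any p_min <= %g selects at least one feature",
      p_min, max(colMeans(x)), max(colMeans(x))))
  }
  dist <- empirical_distribution(x)
  model <- fit_parameters(dist, fs, config)
  if (z_method == "auto") {
    z_method <- if (model$n_neurons <= 20L) "exact" else "good_turing"
  }
  model <- switch(z_method,
    exact = set_log_partition(model, exact_log_partition(model), "exact"),
    good_turing = set_log_partition(
      model, good_turing_log_partition(model, dist), "good_turing"),
    gibbs_silent_state = set_log_partition(
      model, gibbs_silent_state_log_partition(model, ...),
      "gibbs_silent_state"),
    none = model)
  attr(model, "p_min") <- p_min
  model
}
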