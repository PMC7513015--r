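#' Exactly solvable three-neuron toy model
#'
#' Three homogeneous neurons with first- and second-order interactions only:
#' each single-neuron parameter is `-alpha`, each pair parameter `+beta`.
#' All eight pattern probabilities have closed forms depending only on the
#' spike count k:
#' \deqn{P(k=0) = 1/Z,\quad P(k=1) = e^{-\alpha}/Z,\quad
#'   P(k=2) = e^{-2\alpha+\beta}/Z,\quad P(k=3) = e^{-3\alpha+3\beta}/Z,}
#' with \eqn{Z = 1 + 3e^{-\alpha} + 3e^{-2\alpha+\beta} + e^{-3\alpha+3\beta}}.
#' At the default alpha = 1, beta = 1.2 the probabilities are approximately
#' 0.1896 / 0.0698 / 0.0852 / 0.3455 for 0/1/2/3 spikes.
#'
#' @param alpha First-order strength (enters with a negative sign).
#' @param beta Pairwise strength (positive sign).
#' @return A `maxent_model` over 3 neurons with 6 features.
#' @export
toy_model <- function(alpha = 1, beta = 1.2) {
  maxent_model(3L,
               list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L)),
               c(rep(-alpha, 3), rep(beta, 3)))
}

#' Exact pattern distribution of the toy model
#'
#' @inheritParams toy_model
#' @param n_samples Effective sample size attached to the table (so it can be
#'   used as "infinite data" input to fitting routines).
#' @return An `empirical_dist` over all 8 patterns with exact weights.
#' @examples
#' d <- toy_exact_distribution()
#' round(pattern_frequency(d, c(1, 1, 1)), 4)  # 0.3455
#' @export
toy_exact_distribution <- function(alpha = 1, beta = 1.2, n_samples = 1e4) {
  k <- rowSums(key_to_pattern(0:7, 3L))
  logw <- -alpha * k + beta * choose(k, 2)
  p <- exp(logw) / sum(exp(logw))
  distribution_from_probs(key_to_pattern(0:7, 3L), p, n_samples)
}

#' Random pairwise ground-truth population
#'
#' Draws a pairwise maximum entropy model with normally distributed
#' parameters: single-neuron terms with mean -3 and variance 0.25, pair terms
#' with mean 0 and variance 2/N. Under 20 ms bins these settings produce low
#' firing rates (a few Hz) and a broad distribution of weak pairwise
#' correlations, the regime typical of cortical population recordings.
#'
#' @param n_neurons Population size N (>= 2).
#' @param seed Integer seed; same seed, same model.
#' @return A `maxent_model` with all N single and choose(N, 2) pair features.
#' @export
sample_ground_truth_pairwise <- function(n_neurons, seed = 1L) {
  if (n_neurons < 2L) stop("need at least 2 neurons")
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_rng(old_seed))
  set.seed(as.integer(seed))
  singles <- as.list(seq_len(n_neurons))
  pairs <- utils::combn(n_neurons, 2L, simplify = FALSE)
  th_1 <- stats::rnorm(n_neurons, mean = -3, sd = sqrt(0.25))
  th_2 <- stats::rnorm(length(pairs), mean = 0, sd = sqrt(2 / n_neurons))
  maxent_model(n_neurons, c(singles, pairs), c(th_1, th_2))
}

#' Upper-orthant probability of a bivariate standard normal
#'
#' \eqn{P(z_1 > g_1, z_2 > g_2)} for standard normal margins with correlation
#' `lam`; the kernel of Dichotomized Gaussian calibration. Monotone
#' nondecreasing in `lam`.
#'
#' @param g1,g2 Thresholds.
#' @param lam Latent correlation in \[-1, 1\].
#' @return Orthant probability in \[0, 1\].
#' @examples
#' bivariate_orthant_probability(0, 0, 0)    # 0.25
#' bivariate_orthant_probability(0, 0, 0.5)  # 0.25 + asin(0.5)/(2*pi)
#' @export
bivariate_orthant_probability <- function(g1, g2, lam) {
  if (abs(lam) > 1) stop("lam must lie in [-1, 1]")
  if (lam >= 1 - 1e-12) return(stats::pnorm(-max(g1, g2)))
  if (lam <= -1 + 1e-12) return(max(0, 1 - stats::pnorm(g1) - stats::pnorm(g2)))
  mvtnorm::pmvnorm(lower = c(g1, g2), upper = c(Inf, Inf),
                   corr = matrix(c(1, lam, lam, 1), 2),
                   algorithm = mvtnorm::Miwa(steps = 512))[1]
}

#' Dichotomized Gaussian specification
#'
#' @param thresholds Per-neuron latent thresholds gamma_i.
#' @param latent_cov Latent correlation matrix Lambda (unit diagonal).
#' @param target_rates Per-bin spike probabilities the spec was calibrated to.
#' @param target_corr Pairwise Pearson targets.
#' @param bin_width_s Bin width in seconds.
#' @return An object of class `dg_spec`.
#' @export
dg_spec <- function(thresholds, latent_cov, target_rates = NULL,
                    target_corr = NULL, bin_width_s = 0.02) {
  n <- length(thresholds)
  if (!isTRUE(all.equal(dim(latent_cov), c(n, n)))) {
    stop("latent_cov must be N x N")
  }
  if (max(abs(diag(latent_cov) - 1)) > 1e-8) {
    stop("latent_cov must have unit diagonal")
  }
  if (max(abs(latent_cov - t(latent_cov))) > 1e-8) {
    stop("latent_cov must be symmetric")
  }
  structure(list(thresholds = as.numeric(thresholds),
                 latent_cov = latent_cov,
                 target_rates = target_rates, target_corr = target_corr,
                 n_neurons = n, bin_width_s = bin_width_s),
            class = "dg_spec")
}

#' @export
print.dg_spec <- function(x, ...) {
  cat(sprintf("dg_spec: %d neurons, mean target rate %.3g/bin\n",
              x$n_neurons,
              if (is.null(x$target_rates)) NA else mean(x$target_rates)))
  invisible(x)
}

# Frechet-feasible interval for the Pearson correlation of two Bernoullis
feasible_corr_interval <- function(p1, p2) {
  s <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  lo <- (max(0, p1 + p2 - 1) - p1 * p2) / s
  hi <- (min(p1, p2) - p1 * p2) / s
  c(lo, hi)
}

#' Calibrate a Dichotomized Gaussian to target rates and correlations
#'
#' Sets per-neuron thresholds \eqn{\gamma_i = \bar\Phi^{-1}(p_i)} so each
#' binarized margin has the target per-bin probability exactly, then solves
#' each latent pairwise correlation \eqn{\Lambda_{ij}} so the orthant
#' probability matches the target joint spiking probability
#' \eqn{p_i p_j + \rho_{ij}\sqrt{p_i(1-p_i)p_j(1-p_j)}} by bracketed
#' root-finding. Targets outside the Frechet-feasible interval (shrunk by
#' `margin`) are clipped, and the assembled latent matrix is projected to the
#' nearest correlation matrix if it is indefinite; both events are recorded
#' as attributes `clipped` and `projection_distance`.
#'
#' @param target_rates Per-bin spike probabilities in (0, 1).
#' @param target_corr Symmetric matrix of target Pearson correlations.
#' @param tol Root-finding tolerance on the latent correlation.
#' @param margin Shrinkage of the feasible correlation interval before
#'   clipping (default 1e-3).
#' @param bin_width_s Bin width recorded on the spec.
#' @return A `dg_spec`.
#' @export
dg_calibrate <- function(target_rates, target_corr, tol = 1e-9,
                         margin = 1e-3, bin_width_s = 0.02) {
  p <- as.numeric(target_rates)
  if (any(p <= 0) || any(p >= 1)) stop("target rates must lie strictly in (0, 1)")
  n <- length(p)
  if (!isTRUE(all.equal(dim(target_corr), c(n, n)))) {
    stop("target_corr must be N x N")
  }
  gamma <- stats::qnorm(p, lower.tail = FALSE)
  lam <- diag(n)
  clipped <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      rho <- target_corr[i, j]
      iv <- feasible_corr_interval(p[i], p[j])
      width <- iv[2] - iv[1]
      lo <- iv[1] + margin * width
      hi <- iv[2] - margin * width
      if (rho < lo || rho > hi) {
        clipped <- clipped + 1L
        rho <- min(max(rho, lo), hi)
      }
      target_joint <- p[i] * p[j] +
        rho * sqrt(p[i] * (1 - p[i]) * p[j] * (1 - p[j]))
      f <- function(l) {
        bivariate_orthant_probability(gamma[i], gamma[j], l) - target_joint
      }
      root <- stats::uniroot(f, c(-1 + 1e-9, 1 - 1e-9), tol = tol,
                             extendInt = "no")$root
      lam[i, j] <- lam[j, i] <- root
    }
  }
  proj_dist <- 0
  if (min(eigen(lam, symmetric = TRUE, only.values = TRUE)$values) < 0) {
    lam2 <- nearest_correlation(lam)
    proj_dist <- max(abs(lam2 - lam))
    lam <- lam2
  }
  # analytically achieved binary correlations under the (possibly projected)
  # latent matrix: equal to the clipped targets when no projection occurred
  achieved <- diag(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      jp <- bivariate_orthant_probability(gamma[i], gamma[j], lam[i, j])
      achieved[i, j] <- achieved[j, i] <- (jp - p[i] * p[j]) /
        sqrt(p[i] * (1 - p[i]) * p[j] * (1 - p[j]))
    }
  }
  out <- dg_spec(gamma, lam, target_rates = p, target_corr = target_corr,
                 bin_width_s = bin_width_s)
  attr(out, "clipped") <- clipped
  attr(out, "projection_distance") <- proj_dist
  attr(out, "achieved_corr") <- achieved
  out
}

# Higham (2002) alternating projections onto the PSD cone and the unit
# diagonal; returns the nearest correlation matrix in Frobenius norm.
nearest_correlation <- function(a, max_iter = 500L, tol = 1e-12) {
  y <- a
  s <- 0
  for (k in seq_len(max_iter)) {
    r <- y - s
    e <- eigen(r, symmetric = TRUE)
    x <- e$vectors %*% (pmax(e$values, 1e-10) * t(e$vectors))
    s <- x - r
    y_old <- y
    y <- x
    diag(y) <- 1
    if (max(abs(y - y_old)) < tol) break
  }
  d <- 1 / sqrt(diag(y))
  y <- y * tcrossprod(d)
  y <- (y + t(y)) / 2
  diag(y) <- 1
  y
}

#' Sample a spike raster from a Dichotomized Gaussian
#'
#' Draws latent multivariate Gaussian vectors (representing correlated input
#' to the population) and thresholds them: neuron i spikes when
#' \eqn{z_i > \gamma_i}. The DG construction matches rates and pairwise
#' correlations by calibration and induces dense higher-order correlations of
#' the kind seen in cortical data.
#'
#' @param spec A `dg_spec`.
#' @param n_samples Number of time bins.
#' @param seed Integer seed.
#' @return A `spike_raster`.
#' @export
dg_sample <- function(spec, n_samples, seed = 1L) {
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_rng(old_seed))
  set.seed(as.integer(seed))
  n <- spec$n_neurons
  ch <- tryCatch(chol(spec$latent_cov), error = function(e) {
    ev <- eigen(spec$latent_cov, symmetric = TRUE)
    chol(ev$vectors %*% diag(pmax(ev$values, 1e-8)) %*% t(ev$vectors))
  })
  z <- matrix(stats::rnorm(n_samples * n), n_samples, n) %*% ch
  x <- matrix(0L, n_samples, n)
  for (i in seq_len(n)) x[, i] <- as.integer(z[, i] > spec$thresholds[i])
  spike_raster(x, bin_width_s = spec$bin_width_s)
}

#' Draw cortical-like target rates and correlations
#'
#' Firing rates are lognormal with mean 4 Hz and SD 2 Hz (on the Hz scale;
#' the lognormal's underlying normal parameters are solved from that mean and
#' SD), converted to per-bin probabilities via the bin width. Pairwise
#' correlation targets are normal with mean 0.1 and SD 0.05, symmetrized.
#'
#' @param n_neurons Population size N (>= 2).
#' @param seed Integer seed.
#' @param mean_hz,sd_hz Mean and SD of the rate distribution in Hz.
#' @param corr_mean,corr_sd Mean and SD of the correlation targets.
#' @param bin_width_s Bin width in seconds (default 0.02).
#' @return List with `rates` (per-bin probabilities), `rates_hz`, and `corr`
#'   (N x N symmetric matrix, unit diagonal).
#' @export
sample_cortical_targets <- function(n_neurons, seed = 1L, mean_hz = 4,
                                    sd_hz = 2, corr_mean = 0.1,
                                    corr_sd = 0.05, bin_width_s = 0.02) {
  if (n_neurons < 2L) stop("need at least 2 neurons")
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_rng(old_seed))
  set.seed(as.integer(seed))
  sigma2 <- log(1 + (sd_hz / mean_hz)^2)
  mu <- log(mean_hz) - sigma2 / 2
  rates_hz <- stats::rlnorm(n_neurons, meanlog = mu, sdlog = sqrt(sigma2))
  p <- pmin(pmax(rates_hz * bin_width_s, 1e-4), 0.5)
  corr <- diag(n_neurons)
  ut <- upper.tri(corr)
  vals <- stats::rnorm(sum(ut), mean = corr_mean, sd = corr_sd)
  corr[ut] <- vals
  corr <- corr + t(corr) - diag(diag(corr))
  diag(corr) <- 1
  list(rates = p, rates_hz = rates_hz, corr = corr)
}
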