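#' Gibbs sampling from a maximum entropy model
#'
#' Sequential single-site Gibbs updates: visiting sites in fixed order
#' 1..N, neuron i is resampled from its full conditional
#' \eqn{P(x_i = 1 \mid x_{-i}) = \sigma(\Delta_i)} with
#' \eqn{\Delta_i = \log w(x^{i \to 1}) - \log w(x^{i \to 0})}, i.e. the sum of
#' theta over features containing i whose other members are all active. One
#' returned sample corresponds to one full sweep; the chain starts from the
#' silent state.
#'
#' @param model A `maxent_model` (a `log_z` is not required).
#' @param n_samples Number of retained samples (rows of the raster).
#' @param burn_in Number of discarded initial sweeps (default 1000).
#' @param thin Keep every `thin`-th sweep after burn-in (default 1).
#' @param seed Integer seed; identical seeds give identical rasters.
#' @param bin_width_s Bin width recorded on the returned raster.
#' @return A `spike_raster` with `n_samples` rows.
#' @examples
#' m <- toy_model()
#' r <- gibbs_sample(m, 500, burn_in = 100, seed = 1)
#' colMeans(r)
#' @export
gibbs_sample <- function(model, n_samples, burn_in = 1000L, thin = 1L,
                         seed = 1L, bin_width_s = 0.02) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (burn_in < 0 || thin < 0) stop("burn_in and thin must be >= 0")
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_rng(old_seed))
  set.seed(as.integer(seed))
  x <- gibbs_sample_cpp(model$n_neurons, model$features, model$theta,
                        as.integer(n_samples), as.integer(burn_in),
                        as.integer(max(1L, thin)))
  spike_raster(x, bin_width_s = bin_width_s)
}

restore_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Silent-state Gibbs estimate of the log partition function
#'
#' In any model of this family the silent (all-zero) pattern has unnormalized
#' weight 1, so its probability is exactly 1/Z. Sampling from the model and
#' inverting the silent-state frequency therefore estimates Z:
#' \deqn{\log \hat{Z} = -\log \widehat{P}(0\cdots0).}
#' Only usable when the silent state has non-negligible probability.
#'
#' @param model A fitted `maxent_model`.
#' @param n_samples Number of Gibbs sweeps retained (default 1e5).
#' @param burn_in Discarded initial sweeps.
#' @param seed Integer seed.
#' @return log of the estimated partition function.
#' @export
gibbs_silent_state_log_partition <- function(model, n_samples = 1e5,
                                             burn_in = 1000L, seed = 1L) {
  r <- gibbs_sample(model, n_samples, burn_in = burn_in, seed = seed)
  freq <- mean(rowSums(r) == 0L)
  if (freq == 0) {
    stop("the silent state was never sampled; its probability is too small ",
         "for this estimator - use good_turing_log_partition() instead")
  }
  -log(freq)
}
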