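test_that("MPF objective equals N on complete uniform data at theta = 0", {
  for (n in c(3, 4, 5)) {
    d <- empirical_distribution(spike_raster(key_to_pattern(0:(2^n - 1), n)))
    o <- mpf_objective(rep(0, n), as.list(seq_len(n)), d)
    expect_equal(o$value, n, tolerance = 1e-12)
  }
})

test_that("MPF gradient matches central finite differences", {
  d <- toy_exact_distribution()
  feats <- toy_feature_list()
  set.seed(11)
  for (rep in 1:3) {
    th <- rnorm(7, sd = 0.8)
    g <- mpf_objective(th, feats, d)$gradient
    fd <- vapply(seq_along(th), function(i) {
      h <- 1e-6
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      (mpf_objective(tp, feats, d)$value -
         mpf_objective(tm, feats, d)$value) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-5)
  }
  expect_error(mpf_objective(c(th[-1], NaN), feats, d), "finite")
})

test_that("MPF is stationary at the truth when the data equal the model", {
  d <- toy_exact_distribution()
  g <- mpf_objective(toy_truth_theta, toy_feature_list(), d)$gradient
  expect_lt(sqrt(sum(g^2)), 1e-6)
})

test_that("both fitters recover the toy ground truth from its exact distribution", {
  d <- toy_exact_distribution()
  m_ml <- fit_parameters(d, toy_feature_list(), fit_config(method = "exact_ml"))
  expect_lt(max(abs(m_ml$theta - toy_truth_theta)), 1e-4)
  m_mpf <- fit_parameters(d, toy_feature_list(), fit_config(method = "mpf"))
  expect_lt(max(abs(m_mpf$theta - toy_truth_theta)), 1e-3)
  expect_lt(max(abs(m_ml$theta - m_mpf$theta)), 1e-3)
  expect_true(attr(m_ml, "converged"))
  expect_true(attr(m_mpf, "converged"))
})

test_that("a balanced single neuron fits to theta = 0", {
  r <- spike_raster(matrix(c(0, 1), 10, 1))
  m <- fit_parameters(empirical_distribution(r), list(1L))
  expect_equal(m$theta, 0, tolerance = 1e-8)
})

test_that("exact-ML matches data moments for random downward-closed sets", {
  for (seed in 1:4) {
    r <- random_raster(400, 5, seed + 50, p = runif(5, 0.25, 0.75))
    fs <- identify_reliable_moments(r, 0.15)
    d <- empirical_distribution(r)
    m <- fit_parameters(d, fs, fit_config(method = "exact_ml", tol = 1e-9))
    fitted_mom <- model_moments_exact(m, fs)
    data_mom <- distribution_moments(d, fs)
    expect_lt(max(abs(fitted_mom - data_mom)), 1e-8)
  }
})

test_that("fits are deterministic", {
  d <- toy_exact_distribution()
  m1 <- fit_parameters(d, toy_feature_list(), fit_config())
  m2 <- fit_parameters(d, toy_feature_list(), fit_config())
  expect_identical(m1$theta, m2$theta)
})

test_that("Good-Turing partition estimate is exact under complete coverage", {
  n <- 4
  m0 <- maxent_model(n, as.list(seq_len(n)), rnorm(n, sd = 0.3))
  r <- spike_raster(key_to_pattern(rep(0:(2^n - 1), 2), n))
  d <- empirical_distribution(r)  # every pattern seen twice: coverage = 1
  expect_equal(good_turing_log_partition(m0, d), exact_log_partition(m0),
               tolerance = 1e-12)
})

test_that("Good-Turing log Z is close to exact on a sampled 10-neuron model", {
  gt <- sample_ground_truth_pairwise(10, seed = 1)
  r <- gibbs_sample(gt, 10000, seed = 2)
  est <- good_turing_log_partition(gt, empirical_distribution(r))
  expect_lt(abs(est - exact_log_partition(gt)), 0.05)
})

test_that("all-singleton data trigger the coverage floor warning", {
  n <- 10
  r <- spike_raster(key_to_pattern(1:50, n))  # 50 distinct patterns, once each
  m0 <- maxent_model(n, as.list(seq_len(n)), rep(0, n))
  expect_warning(good_turing_log_partition(m0, empirical_distribution(r)),
                 "coverage")
})

test_that("fit_rm runs the full pipeline on toy-model data", {
  d <- toy_exact_distribution()
  r <- spike_raster(d$patterns[rep(seq_along(d$keys),
                                   round(d$counts)), , drop = FALSE])
  m <- fit_rm(r, p_min = 0.1, z_method = "exact")
  expect_length(m$features, 7)
  expect_equal(m$z_method, "exact")
  probs <- pattern_probability(m, key_to_pattern(0:7, 3))
  target <- toy_probs_by_count()[rowSums(key_to_pattern(0:7, 3)) + 1]
  expect_lt(max(abs(probs - target)), 1e-3)
  expect_equal(attr(m, "p_min"), 0.1)
})

test_that("fit_rm derives its threshold from alpha_rel when asked", {
  r <- random_raster(500, 4, 77, p = rep(0.4, 4))
  m <- fit_rm(r, alpha_rel = 1, z_method = "none")
  expect_equal(attr(m, "p_min"), threshold_from_error(500, 1))
  expect_error(fit_rm(r, p_min = 0.1, alpha_rel = 1), "exactly one")
})

test_that("an unreachable threshold reports the largest usable p_min", {
  r <- spike_raster(cbind(c(rep(0L, 9), 1L), rep(0L, 10)))  # max rate 0.1
  expect_error(fit_rm(r, p_min = 0.5), "0\\.1")
  expect_error(fit_rm(r, p_min = 1.01), "p_min")
})

test_that("normalized RM fits have nonnegative KL divergence against data", {
  r <- random_raster(600, 4, 13, p = runif(4, 0.2, 0.6))
  m <- fit_rm(r, p_min = 0.05, z_method = "exact")
  d <- empirical_distribution(r)
  q <- pattern_probability(m, d$patterns)
  p <- d$counts / d$n_samples
  kl <- sum(p * log2(p / q))
  expect_gte(kl, 0)
  # and KL is 0 iff the model reproduces the data exactly: the saturated
  # model over the observed support of a 2-neuron raster achieves ~0
  r2 <- spike_raster(key_to_pattern(rep(0:3, c(40, 30, 20, 10)), 2))
  m2 <- fit_rm(r2, p_min = 0.05, z_method = "exact",
               config = fit_config(method = "exact_ml", tol = 1e-10))
  d2 <- empirical_distribution(r2)
  q2 <- pattern_probability(m2, d2$patterns)
  p2 <- d2$counts / d2$n_samples
  expect_lt(sum(p2 * log2(p2 / q2)), 1e-7)
})
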