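test_that("the toy table matches its closed form and the enumeration oracle", {
  d <- toy_exact_distribution()
  probs <- d$counts / d$n_samples
  by_count <- toy_probs_by_count()
  expect_equal(probs, by_count[rowSums(d$patterns) + 1], tolerance = 1e-12)
  expect_equal(round(pattern_frequency(d, c(0, 0, 0)), 4), 0.1896)
  expect_equal(round(pattern_frequency(d, c(1, 1, 1)), 4), 0.3455)

  # arbitrary (alpha, beta) agree with brute-force enumeration of the model
  for (ab in list(c(0, 0), c(0.5, 0.3), c(2, -0.4))) {
    dd <- toy_exact_distribution(ab[1], ab[2])
    m <- toy_model(ab[1], ab[2])
    m <- set_log_partition(m, exact_log_partition(m), "exact")
    expect_equal(dd$counts / dd$n_samples, pattern_probability(m, dd$patterns),
                 tolerance = 1e-12)
  }
  expect_equal(toy_exact_distribution(0, 0)$counts, rep(1250, 8))
})

test_that("pairwise ground-truth populations are seeded and cortical-like", {
  m1 <- sample_ground_truth_pairwise(20, seed = 5)
  m2 <- sample_ground_truth_pairwise(20, seed = 5)
  expect_identical(m1$theta, m2$theta)
  expect_false(identical(m1$theta, sample_ground_truth_pairwise(20, 6)$theta))

  rates <- c()
  corrs <- c()
  for (s in 1:10) {
    gt <- sample_ground_truth_pairwise(20, seed = s)
    r <- gibbs_sample(gt, 3000, burn_in = 500, seed = 100 + s)
    rates <- c(rates, colMeans(r))
    cm <- pearson_correlations(r)
    corrs <- c(corrs, cm[upper.tri(cm)])
  }
  # low per-bin rates (a few Hz at 20 ms bins) ...
  expect_gt(mean(rates), 0.03)
  expect_lt(mean(rates), 0.11)
  # ... and a broad, near-zero-mean distribution of pairwise correlations
  corrs <- corrs[is.finite(corrs)]
  expect_lt(abs(mean(corrs) - 0.01), 0.05)
  expect_gt(sd(corrs), 0.02)
  expect_lt(sd(corrs), 0.10)
})

test_that("bivariate orthant probabilities obey the closed-form identities", {
  expect_equal(bivariate_orthant_probability(0, 0, 0), 0.25, tolerance = 1e-8)
  expect_equal(bivariate_orthant_probability(1.3, -0.4, 0),
               pnorm(-1.3) * pnorm(0.4), tolerance = 1e-8)
  for (lam in c(-0.9, -0.3, 0.4, 0.8)) {
    expect_equal(bivariate_orthant_probability(0, 0, lam),
                 0.25 + asin(lam) / (2 * pi), tolerance = 1e-7)
  }
  # comonotone limit and monotonicity in lam
  expect_equal(bivariate_orthant_probability(0.5, 0.5, 1), pnorm(-0.5))
  v <- vapply(seq(-0.95, 0.95, by = 0.19),
              function(l) bivariate_orthant_probability(0.8, 0.2, l),
              numeric(1))
  expect_true(all(diff(v) >= 0))
})

test_that("DG calibration hits exact marginals and solves pair targets", {
  p <- c(0.08, 0.08)
  spec <- dg_calibrate(p, matrix(c(1, 0.1, 0.1, 1), 2))
  expect_equal(pnorm(spec$thresholds, lower.tail = FALSE), p,
               tolerance = 1e-10)
  joint <- bivariate_orthant_probability(spec$thresholds[1],
                                         spec$thresholds[2],
                                         spec$latent_cov[1, 2])
  expect_equal(joint, p[1] * p[2] + 0.1 * p[1] * (1 - p[1]),
               tolerance = 1e-7)
  # zero targets give the identity latent covariance
  s0 <- dg_calibrate(c(0.2, 0.3, 0.4), diag(3))
  expect_equal(s0$latent_cov, diag(3), tolerance = 1e-7)
  # infeasible targets are clipped and recorded
  s_clip <- dg_calibrate(c(0.05, 0.9), matrix(c(1, 0.9, 0.9, 1), 2))
  expect_gt(attr(s_clip, "clipped"), 0)
})

test_that("DG sampling round-trips rates and correlations (small population)", {
  p <- c(0.08, 0.12, 0.2)
  rho <- matrix(0.1, 3, 3)
  diag(rho) <- 1
  spec <- dg_calibrate(p, rho)
  r <- dg_sample(spec, 2e5, seed = 31)
  expect_true(all(abs(colMeans(r) - p) < 4 * sqrt(p * (1 - p) / 2e5)))
  ch <- pearson_correlations(r)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(abs(ch[i, j] - 0.1), 4 * 1.5 / sqrt(2e5))
  }
  # degenerate edges: infinite thresholds silence the population
  s_inf <- dg_spec(rep(Inf, 3), diag(3))
  expect_true(all(dg_sample(s_inf, 100, seed = 1) == 0))
  # identity latent covariance gives independent neurons
  s_ind <- dg_calibrate(c(0.3, 0.3), diag(2))
  r_ind <- dg_sample(s_ind, 1e5, seed = 32)
  expect_lt(abs(pearson_correlations(r_ind)[1, 2]), 4 / sqrt(1e5))
})

test_that("DG populations carry excess higher-order co-spiking", {
  # dense latent correlations induce third-order moments above the
  # independent (product-of-rates) prediction
  tg <- sample_cortical_targets(20, seed = 1)
  spec <- dg_calibrate(tg$rates, tg$corr)
  r <- dg_sample(spec, 10000, seed = 33)
  set.seed(34)
  triplets <- replicate(60, sort(sample(20, 3)), simplify = FALSE)
  m3 <- empirical_moments(r, triplets)
  indep <- vapply(triplets, function(f) prod(colMeans(r)[f]), numeric(1))
  expect_gt(mean(m3 - indep), 0)
  expect_gt(mean(m3 / pmax(indep, 1e-12)), 1.5)
})

test_that("cortical target draws match the prescribed rate/correlation laws", {
  tg <- sample_cortical_targets(300, seed = 2)
  # lognormal with mean 4 Hz, SD 2 Hz
  expect_lt(abs(mean(tg$rates_hz) - 4), 4 * 2 / sqrt(300))
  expect_lt(abs(sd(tg$rates_hz) - 2), 0.5)
  expect_equal(tg$rates, pmin(pmax(tg$rates_hz * 0.02, 1e-4), 0.5))
  ut <- upper.tri(tg$corr)
  expect_lt(abs(mean(tg$corr[ut]) - 0.1), 4 * 0.05 / sqrt(sum(ut)))
  expect_lt(abs(sd(tg$corr[ut]) - 0.05), 0.005)
  expect_identical(tg$corr, t(tg$corr))
  expect_identical(sample_cortical_targets(10, seed = 9)$rates,
                   sample_cortical_targets(10, seed = 9)$rates)
})
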