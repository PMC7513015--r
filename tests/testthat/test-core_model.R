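test_that("log weights of the toy model match the closed form", {
  m <- toy_model()
  expect_identical(log_weight(m, c(0, 0, 0)), 0)
  expect_equal(log_weight(m, c(1, 0, 0)), -1)
  expect_equal(log_weight(m, c(1, 1, 1)), 0.6)
  # adding a feature that is inactive in the pattern changes nothing
  m2 <- maxent_model(3, c(m$features, list(c(1L, 2L, 3L))), c(m$theta, 5))
  expect_equal(log_weight(m2, c(1, 1, 0)), log_weight(m, c(1, 1, 0)))
  expect_error(log_weight(m, c(1, 0)), "neurons")
})

test_that("exact partition function enumerates all patterns", {
  m0 <- maxent_model(4, list(1, 2, 3, 4), rep(0, 4))
  expect_equal(exact_log_partition(m0), log(16))
  expect_equal(exact_log_partition(toy_model()), log(toy_z()), tolerance = 1e-12)
  big <- maxent_model(26, list(1), 0)
  expect_error(exact_log_partition(big), "good_turing")
})

test_that("toy pattern probabilities reproduce the four spike-count classes", {
  m <- toy_model()
  expect_error(pattern_probability(m, c(0, 0, 0)), "log_z")
  m <- set_log_partition(m, exact_log_partition(m), "exact")
  expect_equal(pattern_probability(m, c(0, 0, 0)), 0.1896, tolerance = 5e-5 / 0.1896)
  expect_equal(pattern_probability(m, c(1, 0, 0)), 0.0698, tolerance = 5e-5 / 0.0698)
  expect_equal(pattern_probability(m, c(0, 1, 1)), 0.0852, tolerance = 5e-5 / 0.0852)
  expect_equal(pattern_probability(m, c(1, 1, 1)), 0.3455, tolerance = 5e-5 / 0.3455)
  all8 <- key_to_pattern(0:7, 3)
  expect_equal(sum(pattern_probability(m, all8)), 1, tolerance = 1e-10)
})

test_that("normalization holds exactly for random models", {
  set.seed(7)
  for (n in c(5, 8)) {
    feats <- c(as.list(seq_len(n)), utils::combn(n, 2, simplify = FALSE))
    m <- maxent_model(n, feats, rnorm(length(feats)))
    m <- set_log_partition(m, exact_log_partition(m), "exact")
    expect_equal(sum(pattern_probability(m, key_to_pattern(0:(2^n - 1), n))),
                 1, tolerance = 1e-10)
  }
})

test_that("empirical distributions count distinct rows", {
  r <- spike_raster(matrix(rep(c(1, 0, 1), each = 4), 4, 3))
  d <- empirical_distribution(r)
  expect_equal(length(d$keys), 1L)
  expect_equal(d$counts, 4)
  expect_equal(d$keys, pattern_key(c(1, 0, 1)))

  r2 <- spike_raster(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)))
  d2 <- empirical_distribution(r2)
  expect_equal(sum(d2$counts), 3)
  expect_equal(pattern_frequency(d2, c(0, 0, 0)), 2 / 3)
  expect_equal(pattern_frequency(d2, c(1, 1, 1)), 1 / 3)
  expect_equal(pattern_frequency(d2, c(1, 0, 0)), 0)
})

test_that("empirical moments are the marginal co-spiking probabilities", {
  ones <- spike_raster(matrix(1, 5, 3))
  zeros <- spike_raster(matrix(0, 5, 3))
  expect_equal(empirical_moments(ones, list(c(1, 3))), 1)
  expect_equal(empirical_moments(zeros, list(2, c(1, 2, 3))), c(0, 0))
  r <- spike_raster(rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(1, 1, 0)))
  expect_equal(empirical_moments(r, list(c(1, 2))), 0.5)
})

test_that("moment hierarchy holds on random rasters", {
  for (seed in 1:5) {
    r <- random_raster(200, 6, seed)
    feats <- list(c(1, 2, 3), c(1, 2), c(2, 3), 2L, c(4, 5, 6), c(4, 5), 5L)
    mom <- empirical_moments(r, feats)
    expect_lte(mom[1], min(mom[2], mom[3]))
    expect_lte(mom[2], mom[4])
    expect_lte(mom[5], mom[6])
    expect_lte(mom[6], mom[7])
  }
})

test_that("exact model moments agree with closed forms and sampling", {
  m0 <- maxent_model(3, list(1, 2, 3), rep(0, 3))
  expect_equal(model_moments_exact(m0, list(1, 2, 3)), rep(0.5, 3))

  m <- toy_model()
  z <- toy_z()
  expect_equal(model_moments_exact(m, list(1)),
               (exp(-1) + 2 * exp(-0.8) + exp(0.6)) / z, tolerance = 1e-12)
  expect_equal(model_moments_exact(m, list(c(1, 2, 3))), 0.3455,
               tolerance = 5e-5 / 0.3455)

  # Gibbs-sampled moments agree with enumeration within Monte-Carlo error
  r <- gibbs_sample(m, 20000, burn_in = 500, seed = 1)
  feats <- list(1, c(1, 2), c(1, 2, 3))
  mh <- empirical_moments(r, feats)
  me <- model_moments_exact(m, feats)
  se <- sqrt(me * (1 - me) / 20000)
  expect_true(all(abs(mh - me) < 4 * se))
})

test_that("first-order-only models factorize into independent logistic rates", {
  th <- c(-2, 0.5, -0.7, 1.1)
  m <- maxent_model(4, as.list(1:4), th)
  rates <- model_moments_exact(m, as.list(1:4))
  expect_equal(rates, exp(th) / (1 + exp(th)), tolerance = 1e-12)
  # and pair moments are products of the rates (independence)
  pm <- model_moments_exact(m, list(c(1, 2), c(3, 4)))
  expect_equal(pm, c(rates[1] * rates[2], rates[3] * rates[4]),
               tolerance = 1e-12)
})

test_that("binary validation is strict and informative", {
  expect_error(spike_raster(matrix(c(0, 1, 2, 1), 2, 2)), "row 1, column 2")
  expect_error(spike_raster(matrix(c(0, 1, 0.999, 1), 2, 2)), "non-binary")
  expect_error(spike_raster(matrix(numeric(0), 0, 0)), "at least one")
})

test_that("pattern keys round-trip and use neuron 1 as the low bit", {
  expect_identical(pattern_key(c(1, 0, 0)), 1L)
  expect_identical(pattern_key(c(0, 0, 1)), 4L)
  keys <- c(0L, 5L, 7L, 2L)
  expect_identical(pattern_key(key_to_pattern(keys, 3)), keys)
})
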