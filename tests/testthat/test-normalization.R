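test_that("percentile normalization is affine-invariant and idempotent", {
  withr::local_seed(10)
  img <- matrix(rgamma(1e4, 2, 0.1), 100)
  n1 <- percentile_normalize(img)
  # affine invariance: normalize(a I + b) = normalize(I), a > 0
  expect_equal(percentile_normalize(3.7 * img + 11), n1, tolerance = 1e-12)
  # the normalized image is a fixed point of the normalizer
  expect_equal(percentile_normalize(n1), n1, tolerance = 1e-12)
  # percentiles of the normalized ramp are exactly 0 and 1
  ramp <- matrix(seq(0, 1000, length.out = 1e6), 1000)
  nr <- percentile_normalize(ramp)
  q <- quantile(nr, c(0.02, 0.998), names = FALSE)
  expect_equal(q, c(0, 1), tolerance = 1e-12)
  expect_error(percentile_normalize(matrix(5, 10, 10)), "degenerate")
  expect_error(normalization_params(50, 20), "p_low")
})

test_that("Anscombe transform hits its closed-form values", {
  expect_equal(anscombe_transform(matrix(0, 3, 3)),
               matrix(2 * sqrt(3 / 8), 3, 3), tolerance = 1e-12)
  expect_equal(anscombe_transform(matrix(13 / 8, 1, 2))[1], 2 * sqrt(2),
               tolerance = 1e-12)
  expect_error(anscombe_transform(matrix(-0.5, 2, 2)), "3/8")
})

test_that("Anscombe transform stabilizes Poisson variance", {
  withr::local_seed(20)
  for (lambda in c(10, 100)) {
    draws <- matrix(rpois(1e5, lambda), 500)
    v <- var(as.vector(anscombe_transform(draws)))
    expect_lt(abs(v - 1), 0.05)
  }
})

test_that("pseudo-residual MAD estimator recovers the noise level", {
  const <- matrix(7, 16, 16)
  st <- estimate_noise_stats(const)
  expect_identical(st$mu_hat, 7)
  expect_identical(st$sigma_hat, 0)

  withr::local_seed(21)
  noise <- matrix(rnorm(512^2, 100, 5), 512)
  st2 <- estimate_noise_stats(noise)
  expect_lt(abs(st2$sigma_hat - 5) / 5, 0.05)
  expect_equal(st2$mu_hat, 100, tolerance = 0.1)

  # piecewise-flat structure barely perturbs the estimate
  steps <- matrix(rep(c(0, 50, 120, 30), each = 128 * 512), 512)
  st3 <- estimate_noise_stats(steps + matrix(rnorm(512^2, 0, 2), 512))
  expect_lt(abs(st3$sigma_hat - 2) / 2, 0.05)
})

test_that("Z-score maps are centered and have Gaussian tails on pure noise", {
  withr::local_seed(22)
  noise <- matrix(rnorm(512^2, 50, 3), 512)
  st <- estimate_noise_stats(noise)
  z <- zscore_map(noise, st)
  # a pixel sitting exactly at the noise mean maps to Z = 0
  at_mu <- zscore_map(matrix(st$mu_hat, 2, 2), st)
  expect_identical(at_mu, matrix(0, 2, 2))
  frac3 <- mean(abs(z) > 3)
  expect_gt(frac3, 0.0027 / 2)
  expect_lt(frac3, 0.0027 * 2)
  # a bright object stands far above the threshold
  noise[100:120, 100:120] <- 50 + 50 * st$sigma_hat
  z2 <- zscore_map(noise, st)
  expect_gt(min(z2[100:120, 100:120]), 30)
  expect_error(zscore_map(noise, structure(list(mu_hat = 0, sigma_hat = 0),
                                           class = "noise_stats")),
               "sigma_hat")
})
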