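test_that("Gaussian blur matches the analytic kernel and conserves mass", {
  img <- matrix(0, 65, 65)
  img[33, 33] <- 1
  out <- gaussian_blur(img, 3.25)
  radius <- ceiling(4 * 3.25)
  k <- exp(-0.5 * (-radius:radius)^2 / 3.25^2)
  k <- k / sum(k)
  expected <- outer(k, k)
  idx <- 33 + (-radius:radius)
  expect_equal(out[idx, idx], expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(out), 1, tolerance = 1e-6)

  # interior-supported image: total intensity conserved
  withr::local_seed(1)
  img2 <- matrix(0, 128, 128)
  img2[40:90, 40:90] <- runif(51 * 51)
  expect_equal(sum(gaussian_blur(img2, 2)), sum(img2), tolerance = 1e-6)

  expect_identical(gaussian_blur(img2, 0), img2)
  expect_error(gaussian_blur(img2, -1), "sigma")
})

test_that("Poisson-Gaussian noise has the model mean and variance", {
  expect_identical(add_poisson_gaussian_noise(matrix(0, 10, 10), 0, seed = 1),
                   matrix(0, 10, 10))
  flat <- matrix(100, 1000, 1000)
  noisy <- add_poisson_gaussian_noise(flat, 4, seed = 2)
  expect_equal(mean(noisy), 100, tolerance = 0.01)
  expect_equal(var(as.vector(noisy)), 116, tolerance = 116 * 0.03)
  # seed-reproducible
  expect_identical(noisy, add_poisson_gaussian_noise(flat, 4, seed = 2))
  expect_error(add_poisson_gaussian_noise(matrix(-1, 2, 2), 1),
               "non-negative")
})

test_that("degradation composes blur then noise with fixed order", {
  img <- matrix(runif(64 * 64, 0, 200), 64)
  expect_identical(degrade(img, degradation_params(0, 0)), img)
  p <- degradation_params(seed = 7)
  expect_identical(degrade(img, p), degrade(img, p))
  # flat-region variance approximately mean + sigma_noise^2
  flat <- matrix(50, 600, 600)
  d <- degrade(flat, degradation_params(sigma_blur = 2, sigma_noise = 3,
                                        seed = 1))
  expect_equal(var(as.vector(d)), 50 + 9, tolerance = 59 * 0.05)
})

test_that("Richardson-Lucy enhancement sharpens ridges, stays non-negative", {
  s <- generate_phantom(small_phantom_config(seed = 9))
  blurred <- gaussian_blur(s$hr_image, 2)
  enhanced <- richardson_lucy_enhance(blurred, psf_sigma = 2, n_iter = 10)
  expect_true(all(enhanced >= 0))
  # ridge contrast along the tube axis strictly increases
  contrast <- function(img) {
    pr <- centerline_profile(s, 1, image = img)
    v <- pr$intensity[pr$intensity > 0]
    (max(v) - min(v)) / (max(v) + min(v))
  }
  expect_gt(contrast(enhanced), contrast(blurred))
  # delta PSF is a fixed point
  expect_identical(richardson_lucy_enhance(blurred, 0, 5), blurred)
  expect_error(richardson_lucy_enhance(matrix(0, 8, 8), 1, 5), "zero total")
})

test_that("width rescaling computes the documented factors", {
  img <- matrix(runif(100 * 80), 100)
  r <- rescale_to_width(img, measured_width = 15.64)
  expect_identical(r$factor, 1)
  expect_identical(r$image, img)
  r8 <- rescale_to_width(img, measured_width = 8)
  expect_equal(r8$factor, 1.955, tolerance = 1e-3)
  expect_identical(dim(r8$image), c(196L, 156L))
  expect_error(rescale_to_width(img, 0), "measured_width")
  # published preprocessing factors for other modalities
  expect_equal(rescale_to_width(img, 15.64 / 2.6)$factor, 2.6,
               tolerance = 1e-12)
  expect_equal(rescale_to_width(img, 15.64 / 4.16)$factor, 4.16,
               tolerance = 1e-12)
  # masks resample without interpolation artifacts
  mask <- matrix(FALSE, 40, 40); mask[10:20, 10:20] <- TRUE
  up <- rescale_mask(mask, 2)
  expect_true(is.logical(up))
  expect_equal(mean(up), mean(mask), tolerance = 0.05)
})

test_that("training width in physical units matches the printed value", {
  expect_equal(width_px_to_nm(15.64, 25), 391, tolerance = 1e-12)
})
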