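test_that("masked NRMSE follows its closed forms and masking semantics", {
  withr::local_seed(70)
  y <- matrix(runif(64^2), 64)
  expect_identical(masked_nrmse(y, y), 0)
  expect_identical(masked_nrmse(y, y, y > 0.5), 0)
  # checkerboard vs zero prediction: RMSE sqrt(0.5), range 1
  cb <- matrix((row(matrix(0, 32, 32)) + col(matrix(0, 32, 32))) %% 2, 32)
  expect_equal(masked_nrmse(cb, matrix(0, 32, 32)), sqrt(0.5),
               tolerance = 1e-12)
  # mask restricted to the perfect half scores zero; full image does not
  yh <- y
  yh[, 33:64] <- 0
  left <- matrix(FALSE, 64, 64); left[, 1:32] <- TRUE
  expect_identical(masked_nrmse(y, yh, left), 0)
  expect_gt(masked_nrmse(y, yh), 0)
  # mean normalization variant
  expect_equal(masked_nrmse(cb, matrix(0, 32, 32), normalization = "mean"),
               sqrt(0.5) / 0.5, tolerance = 1e-12)
  expect_error(masked_nrmse(y, yh, matrix(FALSE, 64, 64)), "empty")
  expect_error(masked_nrmse(matrix(1, 4, 4), matrix(0, 4, 4)), "zero")
})

test_that("masked PSNR matches closed forms and sentinels", {
  y <- matrix(rep(c(0, 1), 128), 16)
  yh <- y + 0.5  # MSE 0.25 on range-1 data
  expect_equal(masked_psnr(y, yh), 10 * log10(4), tolerance = 1e-12)
  expect_identical(masked_psnr(y, y), Inf)
  # errors concentrated outside the mask: masked value exceeds the full one
  withr::local_seed(71)
  y2 <- matrix(runif(64^2), 64)
  y2h <- y2
  y2h[1:32, ] <- y2h[1:32, ] + 0.3
  bottom <- matrix(FALSE, 64, 64); bottom[33:64, ] <- TRUE
  expect_gt(masked_psnr(y2, y2h, bottom), masked_psnr(y2, y2h))
})

test_that("masked SSIM restricts the full-image map", {
  withr::local_seed(72)
  y <- matrix(runif(96^2), 96)
  expect_equal(masked_ssim(y, y, y > 0.3), 1, tolerance = 1e-12)
  all_mask <- matrix(TRUE, 96, 96)
  yh <- y + matrix(rnorm(96^2, 0, 0.2), 96)
  expect_identical(masked_ssim(y, yh, all_mask), masked_ssim(y, yh))
  # independent noise fields are structurally unrelated
  a <- matrix(rnorm(96^2), 96); b <- matrix(rnorm(96^2), 96)
  expect_lt(abs(masked_ssim(a, b, all_mask)), 0.1)
})

test_that("dataset evaluation aggregates the nine metrics per image", {
  withr::local_seed(73)
  mk <- function(perfect) {
    y <- matrix(runif(64^2), 64)
    mito <- matrix(FALSE, 64, 64); mito[16:48, 16:48] <- TRUE
    cris <- matrix(FALSE, 64, 64); cris[24:40, 24:40] <- TRUE
    list(pair = list(pred = if (perfect) y else y + rnorm(64^2, 0, 0.1),
                     target = y),
         mask = list(mito = mito, cristae = cris))
  }
  items <- lapply(c(TRUE, FALSE, FALSE), mk)
  csv <- withr::local_tempfile(fileext = ".csv")
  rep <- suppressWarnings(
    evaluate_dataset(lapply(items, `[[`, "pair"),
                     lapply(items, `[[`, "mask"), csv = csv))
  expect_s3_class(rep, "metrics_report")
  expect_identical(nrow(rep$per_image), 3L)
  expect_identical(nrow(rep$summary), 9L)
  expect_true(file.exists(csv))
  # perfect image contributes 0 / Inf-sentinel / 1
  expect_identical(rep$per_image$full.nrmse[1], 0)
  expect_identical(rep$per_image$full.psnr[1], Inf)
  expect_equal(rep$per_image$cristae.ssim[1], 1, tolerance = 1e-12)
  # sentinel excluded from aggregation with a warning
  expect_warning(evaluate_dataset(lapply(items, `[[`, "pair"),
                                  lapply(items, `[[`, "mask")),
                 "sentinel")
  psnr_row <- subset(rep$summary, scope == "full" & metric == "psnr")
  expect_identical(psnr_row$n, 2L)
})

test_that("Gaussian FWHM fitting matches the closed form and drops flats", {
  x <- seq(0, 40, by = 0.25)
  prof <- data.frame(position_px = x,
                     intensity = 3 * exp(-(x - 20)^2 / (2 * 2^2)) + 1)
  fit <- fwhm_width(prof, pixel_size = 25)
  expect_equal(fit$fwhm_nm, 2 * sqrt(2 * log(2)) * 2 * 25,
               tolerance = 1e-3 * 117.74)
  expect_equal(fit$sigma, 2, tolerance = 1e-4)
  # unbiased across the physically relevant width range
  for (s0 in c(1, 3, 6)) {
    pr <- data.frame(position_px = x,
                     intensity = exp(-(x - 18)^2 / (2 * s0^2)))
    expect_lt(abs(fwhm_width(pr, 25)$sigma - s0) / s0, 1e-3)
  }
  # moderate noise keeps the estimate within 10%
  withr::local_seed(74)
  errs <- sapply(1:20, function(i) {
    pr <- data.frame(position_px = x,
                     intensity = 3 * exp(-(x - 20)^2 / 8) + 1 +
                       rnorm(length(x), 0, 0.15))
    abs(fwhm_width(pr, 25)$fwhm_nm - 117.7410) / 117.7410
  })
  expect_lt(max(errs), 0.10)
  expect_error(fwhm_width(data.frame(position_px = x,
                                     intensity = rep(2, length(x))),
                          25), "flat")
})

test_that("peak intervals convert spacings to nm and ignore monotone data", {
  x <- seq(0, 15, by = 0.5)
  v <- numeric(length(x))
  v[x %in% c(2, 7, 12)] <- 1
  prof <- data.frame(position_px = x, intensity = v)
  expect_equal(peak_to_peak_intervals(prof, 0.1, pixel_size = 25),
               c(125, 125))
  mono <- data.frame(position_px = x, intensity = x)
  expect_identical(peak_to_peak_intervals(mono, 0.1, pixel_size = 25),
                   numeric(0))
  # prominence threshold suppresses riding ripples
  rip <- data.frame(position_px = x,
                    intensity = sin(x) + 0.02 * sin(20 * x))
  iv <- peak_to_peak_intervals(rip, 0.1, pixel_size = 1)
  expect_equal(mean(iv), 2 * pi, tolerance = 0.2)
})

test_that("line profiles sample straight segments with physical positions", {
  img <- matrix(rep(seq_len(64), each = 64), 64)  # ramp along columns
  pr <- line_profile(img, from = c(10, 5), to = c(10, 55), pixel_size = 25)
  expect_s3_class(pr, "line_profile")
  expect_gt(nrow(pr), 5)
  expect_true(all(diff(pr$position_px) > 0))
  expect_equal(pr$position_nm, pr$position_px * 25)
  # intensity along the ramp is linear in distance
  co <- coef(lm(pr$intensity ~ pr$position_px))
  expect_equal(unname(co[2]), 1, tolerance = 1e-6)
  expect_error(line_profile(img, c(3, 3), c(3, 3)), "zero length")
})
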