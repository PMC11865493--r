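test_that("phantom generation is deterministic and geometrically consistent", {
  cfg <- small_phantom_config(seed = 11)
  s1 <- generate_phantom(cfg)
  s2 <- generate_phantom(cfg)
  expect_identical(s1, s2)

  expect_true(all(s1$hr_image >= 0))
  expect_identical(dim(s1$hr_image), dim(s1$mito_mask))
  expect_identical(dim(s1$hr_image), dim(s1$cristae_mask))
  # cristae are a subset of mitochondria
  expect_false(any(s1$cristae_mask & !s1$mito_mask))
  # foreground peaks sit in the configured intensity range
  expect_lte(max(s1$hr_image), max(cfg$fg_intensity_range))
  expect_gt(max(s1$hr_image), cfg$bg_level)
})

test_that("a tube-free configuration renders pure background", {
  cfg <- small_phantom_config(seed = 3, n_tubes = 0L)
  s <- generate_phantom(cfg)
  expect_true(all(s$hr_image == cfg$bg_level))
  expect_false(any(s$mito_mask))
  expect_false(any(s$cristae_mask))
  expect_identical(nrow(s$tubes), 0L)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(image_size = c(64, 256)), "image_size")
  expect_error(phantom_config(tube_width_mean = 2, crista_width = 3.5),
               "crista_width")
  expect_error(phantom_config(fg_intensity_range = c(300, 56)), "fg")
  expect_error(phantom_config(bg_level = 100), "fg")
})

test_that("datasets are reproducible, distinct per image, and plausible", {
  cfg <- small_phantom_config(seed = 40)
  d1 <- generate_dataset(cfg, 6)
  d2 <- generate_dataset(cfg, 6)
  expect_identical(d1, d2)
  # geometries differ between samples
  widths <- t(sapply(d1, function(s) s$tubes$width))
  expect_gt(nrow(unique(widths)), 5)
  # mitochondrial coverage stays in a plausible band
  fracs <- sapply(d1, function(s) mean(s$mito_mask))
  expect_true(all(fracs > 0.05 & fracs < 0.40))
})

test_that("drawn tube widths match the configured distribution", {
  # location check over 1000 drawn widths
  cfg <- phantom_config(image_size = c(128L, 128L), n_tubes = 10L, seed = 7)
  widths <- unlist(lapply(generate_dataset(cfg, 100), function(s)
    s$tubes$width))
  expect_length(widths, 1000L)
  expect_lt(abs(mean(widths) - 15.64), 0.5)
})

test_that("rendered tube widths measure close to the drawn widths", {
  # half-max transverse width on noiseless single-tube renders, paired
  # against the width each tube was drawn with
  cfg <- phantom_config(image_size = c(192L, 192L), n_tubes = 1L, seed = 1)
  err <- sapply(1:40, function(i) {
    cfg$seed <- 1000 + i
    s <- generate_phantom(cfg)
    m <- tube_width_measured(s)
    if (is.finite(m)) m - s$tubes$width else NA_real_
  })
  err <- err[is.finite(err)]
  expect_gt(length(err), 30)
  expect_lt(abs(mean(err)) / 15.64, 0.05)
})

test_that("ridge spacing is recovered by peak intervals on noiseless tubes", {
  cfg <- phantom_config(image_size = c(192L, 192L), n_tubes = 2L, seed = 2)
  per_tube <- c()
  for (i in 1:55) {
    cfg$seed <- 3000 + i
    s <- generate_phantom(cfg)
    for (tb in seq_len(nrow(s$tubes))) {
      iv <- peak_to_peak_intervals(centerline_profile(s, tb), 0.1)
      if (length(iv) >= 3) per_tube <- c(per_tube, mean(iv))
    }
  }
  expect_gte(length(per_tube), 100)
  # intervals in nm; configured spacing 5 px at 25 nm/px = 125 nm
  expect_lt(abs(mean(per_tube) - 125) / 125, 0.10)
})

test_that("phantom datasets export as TIFFs with a manifest", {
  dir <- withr::local_tempdir()
  d <- generate_dataset(small_phantom_config(seed = 5), 2)
  manifest <- write_phantom_dataset(d, dir)
  expect_identical(nrow(manifest), 2L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_image(file.path(dir, "phantom_001_hr.tif"))
  expect_equal(back, d[[1]]$hr_image, tolerance = 1e-6,
               ignore_attr = TRUE)
  mito <- read_image(file.path(dir, "phantom_001_mito.tif"))
  expect_equal(mito > 0.5, d[[1]]$mito_mask, ignore_attr = TRUE)
})
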