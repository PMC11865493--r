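test_that("adaptive thresholding stops at the first satisfied fraction", {
  withr::local_seed(30)
  z <- matrix(abs(rnorm(100 * 100, 0, 0.5)), 100)
  z[1:45, 1:45] <- 50  # ~20% of pixels far above the starting threshold
  mask <- adaptive_threshold_mask(z, sampling_config())
  expect_gt(mean(mask & z > 30), 0.19)
  expect_lt(mean(mask & z <= 30), 0.01)
})

test_that("the threshold loop decrements to reach the fraction or floors", {
  withr::local_seed(31)
  # no object: mask must still reach the minimum fraction via decrements
  z <- matrix(rnorm(200 * 200), 200)
  mask <- suppressWarnings(adaptive_threshold_mask(z, sampling_config()))
  # pure noise yields tiny masks only if the floor warning fired
  expect_warning(adaptive_threshold_mask(z, sampling_config()),
                 "floor")
  # an image with enough moderately bright pixels satisfies 10% exactly
  z2 <- matrix(0, 100, 100)
  z2[1:40, 1:40] <- 12
  m2 <- adaptive_threshold_mask(z2, sampling_config())
  expect_gte(mean(m2), 0.10)
})

test_that("the Z-score mask is invariant to affine shifts of the input", {
  withr::local_seed(32)
  img <- matrix(rnorm(128^2, 10, 1), 128)
  img[40:80, 40:80] <- img[40:80, 40:80] + 40
  chain <- function(x) {
    st <- estimate_noise_stats(x)
    adaptive_threshold_mask(zscore_map(x, st), sampling_config())
  }
  expect_identical(chain(img), chain(img + 5))
  expect_identical(chain(img), chain(2 * img))
})

test_that("ROI centers respect mask, margins, spacing and target count", {
  cfg <- sampling_config(seed = 33)
  mask <- matrix(TRUE, 256, 512)
  centers <- select_roi_centers(mask, cfg)
  expect_identical(nrow(centers), 8L)  # floor(256/128) * floor(512/128)
  for (run in 1:20) {
    cfg$seed <- 100 + run
    ctr <- suppressWarnings(select_roi_centers(mask, cfg))
    expect_true(all(ctr[, "row"] >= 64 & ctr[, "row"] <= 192))
    expect_true(all(ctr[, "col"] >= 64 & ctr[, "col"] <= 448))
    if (nrow(ctr) > 1) {
      d <- as.matrix(dist(ctr))
      expect_true(all(d[upper.tri(d)] >= 60))
    }
  }
  # a single small blob admits only one center
  blob <- matrix(FALSE, 256, 256)
  blob[120:130, 120:130] <- TRUE
  expect_warning(ctr1 <- select_roi_centers(blob, cfg), "admit only")
  expect_identical(nrow(ctr1), 1L)
  expect_error(select_roi_centers(matrix(FALSE, 256, 256), cfg),
               "eligible")
})

test_that("augmentation quadruples pairs and keeps them co-registered", {
  withr::local_seed(34)
  pairs <- lapply(1:24, function(i)
    list(lr = matrix(rnorm(64^2), 64), hr = matrix(rnorm(64^2), 64)))
  aug <- augment_pairs(pairs, seed = 35)
  expect_length(aug, 96L)
  n_extra <- sum(sapply(aug, function(p) attr(p, "transform")$extra))
  expect_identical(n_extra, 24L)  # 25% of the augmented set

  rot_ccw <- function(m, k) { while (k > 0) { m <- t(m)[rev(seq_len(ncol(m))), ]; k <- k - 1 }; m }
  for (p in aug[seq(1, 96, by = 7)]) {
    tr <- attr(p, "transform")
    src <- pairs[[tr$source]]
    if (!tr$extra) {
      # pure rotations invert exactly
      expect_equal(rot_ccw(p$lr, (4 - tr$rot) %% 4), src$lr,
                   ignore_attr = TRUE)
      expect_equal(rot_ccw(p$hr, (4 - tr$rot) %% 4), src$hr,
                   ignore_attr = TRUE)
    } else {
      # replaying the recorded transform reproduces both members
      redo <- mitorestore:::apply_pair_transform(
        rot_ccw(src$lr, tr$rot) * 0 + rot_ccw(src$lr, tr$rot), 0, TRUE,
        tr$shrink_factor)
      expect_equal(redo, p$lr, ignore_attr = TRUE)
      redo_hr <- mitorestore:::apply_pair_transform(rot_ccw(src$hr, tr$rot),
                                                    0, TRUE,
                                                    tr$shrink_factor)
      expect_equal(redo_hr, p$hr, ignore_attr = TRUE)
    }
  }
  expect_error(augment_pairs(list(list(lr = matrix(0, 4, 4),
                                       hr = matrix(0, 5, 5)))),
               "shape")
})

test_that("the end-to-end patch builder yields valid, split patch pairs", {
  cfg <- small_phantom_config(seed = 36, n_tubes = 3L)
  hr <- lapply(generate_dataset(cfg, 2), `[[`, "hr_image")
  sc <- sampling_config(seed = 37)
  ts <- build_training_set(hr, degradation_params(seed = 38),
                           normalization_params(), sc, rl_psf_sigma = 0)
  all_p <- c(ts$train, ts$validation)
  expect_gt(length(all_p), 3)
  # 80/20 split up to rounding on a small patch count
  expect_identical(length(ts$validation),
                   as.integer(max(1, round(0.2 * length(all_p)))))
  origins <- t(sapply(all_p, `[[`, "origin"))
  expect_identical(nrow(unique(origins)), nrow(origins))  # disjoint split
  for (p in all_p) {
    expect_identical(dim(p$lr), c(128L, 128L))
    expect_identical(dim(p$hr), c(128L, 128L))
    expect_true(all(p$gamma %in% c(1, 4)))
  }
  # sampler bias: patches are richer in mitochondria than the frame average
  img_frac <- mean(sapply(generate_dataset(cfg, 2),
                          function(s) mean(s$mito_mask)))
  patch_frac <- mean(sapply(all_p, function(p) mean(p$gamma == 1)))
  expect_gt(patch_frac, img_frac)

  # patch stacks export as multi-page TIFF plus a manifest
  dir <- withr::local_tempdir()
  manifest <- write_patches(ts, dir)
  expect_identical(nrow(manifest), length(all_p))
  lr_back <- read_image(file.path(dir, "lr.tif"))
  expect_identical(dim(lr_back)[3], length(all_p))
  expect_equal(lr_back[, , 1], ts$train[[1]]$lr, tolerance = 1e-4,
               ignore_attr = TRUE)
  gam <- read_image(file.path(dir, "gamma.tif"))
  expect_true(all(round(gam[, , 1]) %in% c(1, 4)))
})
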