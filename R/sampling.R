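#' Configuration of the mitochondria-focused patch sampler
#'
#' @param patch_size patch side N in px (>= 32, default 128).
#' @param threshold_start starting Z-score threshold c0 (default 30).
#' @param threshold_step decrement applied while the mitochondrial fraction
#'   is not reached (default 5).
#' @param min_mito_fraction minimum fraction of pixels classified as
#'   mitochondrial (default 0.10).
#' @param min_center_distance minimum Euclidean distance between accepted
#'   ROI centers in px (default 60).
#' @param border_margin minimum distance of a center from every image edge;
#'   defaults to `patch_size / 2` so patches fit without padding.
#' @param max_retries rejection-sampling draws attempted per center.
#' @param seed integer seed for the ROI draw.
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(patch_size = 128L, threshold_start = 30,
                            threshold_step = 5, min_mito_fraction = 0.10,
                            min_center_distance = 60,
                            border_margin = patch_size / 2,
                            max_retries = 1000L, seed = NULL) {
  cfg <- list(patch_size = as.integer(patch_size),
              threshold_start = threshold_start,
              threshold_step = threshold_step,
              min_mito_fraction = min_mito_fraction,
              min_center_distance = min_center_distance,
              border_margin = as.integer(border_margin),
              max_retries = as.integer(max_retries), seed = seed)
  if (cfg$patch_size < 32) stop("patch_size must be >= 32")
  if (cfg$patch_size %% 2 != 0) stop("patch_size must be even")
  if (cfg$threshold_start <= 0) stop("threshold_start must be > 0")
  if (cfg$threshold_step <= 0) stop("threshold_step must be > 0")
  if (!(cfg$min_mito_fraction > 0 && cfg$min_mito_fraction < 1))
    stop("min_mito_fraction must be in (0, 1)")
  if (cfg$min_center_distance < 0) stop("min_center_distance must be >= 0")
  class(cfg) <- "sampling_config"
  cfg
}

#' Adaptive Z-score thresholding of the mitochondria mask
#'
#' Starting from `threshold_start`, the threshold is decremented by
#' `threshold_step` while the set `{Z > c}` holds less than
#' `min_mito_fraction` of the pixels. If the next decrement would make the
#' threshold non-positive, the loop stops at the last positive value with a
#' warning (the adaptive loop has no natural floor, so this guarantees
#' termination on pathological inputs). The raw mask is then cleaned with a
#' single-pass 3x3 binary median filter.
#'
#' @param z finite Z-score matrix (see [zscore_map()]).
#' @param config a [sampling_config()].
#' @return Logical mitochondria mask with attributes `threshold` (the final
#'   threshold c) and `raw_fraction` (the fraction of pixels above it
#'   before median cleanup — the quantity the adaptive loop controls; the
#'   cleanup can only remove pixels).
#' @export
adaptive_threshold_mask <- function(z, config = sampling_config()) {
  check_image(z, "z")
  stopifnot(inherits(config, "sampling_config"))
  target <- config$min_mito_fraction * length(z)
  c0 <- config$threshold_start
  repeat {
    if (sum(z > c0) >= target) break
    cn <- c0 - config$threshold_step
    if (cn <= 0) {
      warning("threshold floor reached at c = ", c0,
              " before the mitochondrial fraction was met")
      break
    }
    c0 <- cn
  }
  mask <- binary_median3(z > c0)
  attr(mask, "threshold") <- c0
  attr(mask, "raw_fraction") <- mean(z > c0)
  mask
}

#' Mitochondria mask straight from an intensity image
#'
#' Convenience chain: Anscombe transform (negatives clamped to zero first;
#' the transform expects count-scale data) -> robust noise statistics ->
#' Z-score map -> adaptive thresholding.
#'
#' @param image numeric matrix on a count-like intensity scale.
#' @param config a [sampling_config()].
#' @return Logical mitochondria mask.
#' @export
mito_mask_from_image <- function(image, config = sampling_config()) {
  ansc <- anscombe_transform(pmax(image, 0))
  stats <- estimate_noise_stats(ansc)
  if (stats$sigma_hat <= 0)
    stop("degenerate image: zero estimated noise level")
  adaptive_threshold_mask(zscore_map(ansc, stats), config)
}

#' Draw ROI centers inside the mitochondria mask
#'
#' Draws up to `N_I = floor(W / N) * floor(L / N)` centers uniformly at
#' random from mask pixels at least `border_margin` from every edge,
#' rejecting candidates closer than `min_center_distance` (Euclidean) to an
#' already accepted center. Because candidates are uniform over mask
#' pixels, regions with more mitochondrial pixels are proportionally more
#' likely to host a patch.
#'
#' @param mask logical mitochondria mask.
#' @param config a [sampling_config()]; its `seed` (if non-NULL) makes the
#'   draw reproducible.
#' @return Integer matrix of accepted centers (columns `row`, `col`,
#'   1-based); a warning is emitted when fewer than `N_I` satisfy the
#'   constraints.
#' @export
select_roi_centers <- function(mask, config = sampling_config()) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  n <- config$patch_size
  n_target <- (h %/% n) * (w %/% n)
  m <- config$border_margin
  eligible <- which(mask)
  rows <- (eligible - 1L) %% h + 1L
  cols <- (eligible - 1L) %/% h + 1L
  keep <- rows >= m & rows <= h - m & cols >= m & cols <= w - m
  rows <- rows[keep]; cols <- cols[keep]
  if (!length(rows))
    stop("no eligible mitochondria pixels after border-margin restriction")
  with_seed(config$seed, {
    acc_r <- integer(0); acc_c <- integer(0)
    while (length(acc_r) < n_target) {
      placed <- FALSE
      for (try in seq_len(config$max_retries)) {
        k <- sample.int(length(rows), 1)
        if (!length(acc_r) ||
            all((acc_r - rows[k])^2 + (acc_c - cols[k])^2 >=
                config$min_center_distance^2)) {
          acc_r <- c(acc_r, rows[k]); acc_c <- c(acc_c, cols[k])
          placed <- TRUE
          break
        }
      }
      if (!placed) break
    }
    if (length(acc_r) < n_target)
      warning("constraints admit only ", length(acc_r), " of ", n_target,
              " ROI centers")
    cbind(row = acc_r, col = acc_c)
  })
}

apply_pair_transform <- function(m, rot, extra, shrink_factor) {
  k <- rot
  while (k > 0) { m <- rotate90(m); k <- k - 1 }
  if (extra) {
    h <- nrow(m); w <- ncol(m)
    h2 <- max(2L, as.integer(round(h * shrink_factor)))
    w2 <- max(2L, as.integer(round(w * shrink_factor)))
    small <- .bicubic_resize_cpp(m, h2, w2)
    pt <- (h - h2) %/% 2; pl <- (w - w2) %/% 2
    m <- pad_reflect(small, pt, h - h2 - pt, pl, w - w2 - pl)
    m <- flip_vertical(flip_horizontal(m))
  }
  m
}

#' Augment co-registered LR/HR image pairs
#'
#' Each pair is expanded into its original plus three quarter-turn rotations
#' (4x count). A seeded random 25% of the augmented set then additionally
#' receives, in order, a shrink transform (isotropic downscale by
#' `shrink_factor`, reflect-padded back to size) and horizontal and vertical
#' flips, applied identically to both members. Duplicates (e.g. rotations of
#' symmetric content) are kept. Each output pair records its transform in
#' attribute `"transform"`.
#'
#' @param pairs list of `list(lr = , hr = )` matrices of identical shape.
#' @param seed integer seed selecting the 25% subset.
#' @param shrink_factor isotropic downscale factor of the shrink transform.
#' @param extra_fraction fraction of the augmented set receiving the extra
#'   transforms.
#' @return List of augmented pairs (length `4 * length(pairs)`).
#' @export
augment_pairs <- function(pairs, seed = NULL, shrink_factor = 0.75,
                          extra_fraction = 0.25) {
  for (p in pairs) {
    check_image(p$lr, "lr"); check_image(p$hr, "hr")
    check_same_shape(p$lr, p$hr, "lr/hr pair")
  }
  out <- list()
  for (i in seq_along(pairs))
    for (rot in 0:3)
      out[[length(out) + 1L]] <-
        list(lr = apply_pair_transform(pairs[[i]]$lr, rot, FALSE, 1),
             hr = apply_pair_transform(pairs[[i]]$hr, rot, FALSE, 1),
             source = i, rot = rot, extra = FALSE)
  with_seed(seed, {
    n_extra <- round(extra_fraction * length(out))
    chosen <- if (n_extra > 0) sample.int(length(out), n_extra) else integer(0)
    for (k in chosen) {
      out[[k]]$lr <- apply_pair_transform(out[[k]]$lr, 0, TRUE, shrink_factor)
      out[[k]]$hr <- apply_pair_transform(out[[k]]$hr, 0, TRUE, shrink_factor)
      out[[k]]$extra <- TRUE
    }
    lapply(out, function(p) {
      res <- list(lr = p$lr, hr = p$hr)
      attr(res, "transform") <- list(source = p$source, rot = p$rot,
                                     extra = p$extra,
                                     shrink_factor = shrink_factor)
      res
    })
  })
}

#' Export patch pairs as multi-page TIFF stacks with a CSV manifest
#'
#' Writes `lr.tif`, `hr.tif` and `gamma.tif` (one page per patch, pages in
#' manifest order) plus `manifest.csv` recording each patch's source image,
#' augmented-pair index, center coordinates and split label.
#'
#' @param sets list with `train` and `validation` patch lists (see
#'   [build_training_set()]).
#' @param dir output directory.
#' @return Invisibly, the manifest data frame.
#' @export
write_patches <- function(sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  patches <- c(sets$train, sets$validation)
  split <- rep(c("train", "validation"),
               c(length(sets$train), length(sets$validation)))
  stack3 <- function(field) {
    n <- nrow(patches[[1]][[field]])
    array(unlist(lapply(patches, `[[`, field)),
          dim = c(n, ncol(patches[[1]][[field]]), length(patches)))
  }
  write_image(stack3("lr"), file.path(dir, "lr.tif"))
  write_image(stack3("hr"), file.path(dir, "hr.tif"))
  write_image(stack3("gamma"), file.path(dir, "gamma.tif"),
              dtype = "uint16")
  manifest <- do.call(rbind, lapply(seq_along(patches), function(i) {
    o <- patches[[i]]$origin
    data.frame(page = i, image = o[["image"]], augmented = o[["augmented"]],
               center_row = o[["row"]], center_col = o[["col"]],
               split = split[i])
  }))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

extract_patch <- function(image, center, n) {
  half <- n %/% 2
  rows <- (center[1] - half + 1):(center[1] + half)
  cols <- (center[2] - half + 1):(center[2] + half)
  image[rows, cols, drop = FALSE]
}

#' Build the training and validation patch sets
#'
#' Full pipeline from HR images to co-registered 128 x 128 patch pairs:
#' for each HR image the LR input is synthesized with [degrade()], the HR
#' target is sharpened with [richardson_lucy_enhance()], the pair is
#' augmented (x4 rotations plus extra transforms on 25%), each augmented LR
#' and HR image is percentile-normalized independently, the mitochondria
#' mask is computed on the raw LR image (count scale, where the Anscombe
#' step is valid), ROI centers are drawn inside it, and co-located patches
#' are cut out together with a per-pixel weight-exponent map
#' (`gamma_inside` on mask pixels, `gamma_outside` elsewhere). Finally the
#' pooled patches are split at random into training and validation sets
#' with no patch in both.
#'
#' @param hr_images list of non-negative HR matrices.
#' @param params a [degradation_params()] (its seed, advanced per image,
#'   drives the noise draws).
#' @param norm a [normalization_params()].
#' @param config a [sampling_config()] (its seed drives ROI draws, the
#'   augmentation subset and the split).
#' @param rl_psf_sigma,rl_n_iter Richardson-Lucy settings for target
#'   enhancement.
#' @param gamma_inside,gamma_outside weight exponents inside/outside the
#'   mitochondria mask (defaults 1 and 4).
#' @param validation_fraction fraction of patches held out for validation.
#' @return List with `train` and `validation`, each a list of `patch_pair`
#'   objects (`lr`, `hr`, `gamma`, `origin`).
#' @export
build_training_set <- function(hr_images, params = degradation_params(),
                               norm = normalization_params(),
                               config = sampling_config(),
                               rl_psf_sigma = 1.5, rl_n_iter = 10,
                               gamma_inside = 1, gamma_outside = 4,
                               validation_fraction = 0.2) {
  stopifnot(length(hr_images) >= 1)
  if (!(validation_fraction > 0 && validation_fraction < 1))
    stop("validation_fraction must be in (0, 1)")
  patches <- list()
  for (i in seq_along(hr_images)) {
    hr <- hr_images[[i]]
    p_i <- params
    if (!is.null(params$seed)) p_i$seed <- params$seed + i
    lr <- degrade(hr, p_i)
    target <- richardson_lucy_enhance(hr, rl_psf_sigma, rl_n_iter)
    aug_seed <- if (is.null(config$seed)) NULL else config$seed + 13L * i
    aug <- augment_pairs(list(list(lr = lr, hr = target)), seed = aug_seed)
    for (j in seq_along(aug)) {
      lr_a <- aug[[j]]$lr; hr_a <- aug[[j]]$hr
      mask <- mito_mask_from_image(lr_a, config)
      lr_n <- percentile_normalize(lr_a, norm)
      hr_n <- percentile_normalize(hr_a, norm)
      cfg_j <- config
      if (!is.null(config$seed)) cfg_j$seed <- config$seed + 1000L * i + j
      centers <- tryCatch(select_roi_centers(mask, cfg_j),
                          error = function(e) NULL)
      if (is.null(centers) || !nrow(centers)) next
      gamma_full <- matrix(gamma_outside, nrow(mask), ncol(mask))
      gamma_full[mask] <- gamma_inside
      for (k in seq_len(nrow(centers))) {
        pp <- list(lr = extract_patch(lr_n, centers[k, ], config$patch_size),
                   hr = extract_patch(hr_n, centers[k, ], config$patch_size),
                   gamma = extract_patch(gamma_full, centers[k, ],
                                         config$patch_size),
                   origin = c(image = i, augmented = j,
                              row = unname(centers[k, 1]),
                              col = unname(centers[k, 2])))
        class(pp) <- "patch_pair"
        patches[[length(patches) + 1L]] <- pp
      }
    }
  }
  if (!length(patches)) stop("no patches could be sampled from the inputs")
  split_seed <- if (is.null(config$seed)) NULL else derive_seed(config$seed,
                                                                "split")
  with_seed(split_seed, {
    n <- length(patches)
    n_val <- max(1L, round(validation_fraction * n))
    idx_val <- sample.int(n, n_val)
    list(train = patches[setdiff(seq_len(n), idx_val)],
         validation = patches[idx_val])
  })
}
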