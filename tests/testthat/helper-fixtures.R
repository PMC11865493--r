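# shared fixture builders; everything is generated in code at test time

small_phantom_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(image_size = c(192L, 192L), n_tubes = 2L,
                                 seed = seed), list(...))
  do.call(phantom_config, args)
}

# a quick co-registered patch pair on a small grid (multiple of 8)
toy_patch <- function(seed, n = 64L) {
  withr::local_seed(seed)
  hr <- matrix(0, n, n)
  hr[(n / 4):(3 * n / 4), (n / 2 - 4):(n / 2 + 4)] <- 1
  hr <- .gauss_blur_cpp(hr, 1)
  lr <- hr + matrix(rnorm(n * n, 0, 0.1), n)
  list(lr = lr, hr = hr, gamma = matrix(ifelse(hr > 0.1, 1, 4), n))
}

# half-max crossing width (px) of a transverse profile through a tube;
# uses the contiguous above-half run containing the profile center, so a
# curved tube re-entering the segment elsewhere is ignored
halfmax_width <- function(profile) {
  v <- profile$intensity
  x <- profile$position_px
  half <- min(v) + (max(v) - min(v)) / 2
  above <- which(v >= half)
  if (length(above) < 2) return(NA_real_)
  mid <- which.min(abs(x - stats::median(range(x))))
  runs <- split(above, cumsum(c(1, diff(above) != 1)))
  run <- NULL
  for (r in runs) if (mid >= min(r) - 1 && mid <= max(r) + 1) run <- r
  if (is.null(run))
    run <- runs[[which.min(sapply(runs, function(r)
      min(abs(r - mid))))]]
  if (length(run) < 2) return(NA_real_)
  i0 <- min(run); i1 <- max(run)
  # linear interpolation at the two crossings
  left <- if (i0 > 1)
    stats::approx(v[c(i0 - 1, i0)], x[c(i0 - 1, i0)], xout = half)$y
  else x[i0]
  right <- if (i1 < length(v))
    stats::approx(v[c(i1 + 1, i1)], x[c(i1 + 1, i1)], xout = half)$y
  else x[i1]
  right - left
}

# transverse intensity profile at a fractional position along a tube's
# centerline; the tangent uses a symmetric 2 px baseline
tube_cross_profile <- function(sample, tube = 1, halfspan = 20, at = 0.5) {
  cl <- sample$centerlines[[tube]]
  mid <- max(9, min(nrow(cl) - 9, round(at * nrow(cl))))
  p0 <- cl[mid, c("row", "col")]
  dp <- cl[mid + 8, c("row", "col")] - cl[mid - 8, c("row", "col")]
  tang <- dp / sqrt(sum(dp^2))
  norm_dir <- c(-tang[2], tang[1])
  line_profile(sample$hr_image,
               from = p0 - halfspan * norm_dir,
               to = p0 + halfspan * norm_dir,
               pixel_size = sample$config$pixel_size, step = 0.1)
}

# robust rendered-width estimate: median of three cross-sections
tube_width_measured <- function(sample, tube = 1) {
  w <- vapply(c(0.4, 0.5, 0.6), function(at)
    halfmax_width(tube_cross_profile(sample, tube, at = at)), numeric(1))
  stats::median(w, na.rm = TRUE)
}
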