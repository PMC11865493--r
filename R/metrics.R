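#' Masked normalized root-mean-square error
#'
#' RMSE over the masked pixels, normalized by the masked dynamic range of
#' the target (`max - min` over the mask) or, with
#' `normalization = "mean"`, by the masked mean. `mask = NULL` evaluates
#' the full image; masked metrics with an all-ones mask equal the unmasked
#' ones exactly.
#'
#' @param y target matrix.
#' @param y_hat prediction matrix.
#' @param mask logical matrix or NULL.
#' @param normalization `"range"` (default) or `"mean"`.
#' @return Scalar NRMSE (>= 0).
#' @export
masked_nrmse <- function(y, y_hat, mask = NULL,
                         normalization = c("range", "mean")) {
  normalization <- match.arg(normalization)
  sel <- metric_selection(y, y_hat, mask)
  denom <- if (normalization == "range") diff(range(sel$y))
           else mean(sel$y)
  if (denom == 0) stop("zero masked dynamic range / mean in the target")
  sqrt(mean((sel$y - sel$y_hat)^2)) / denom
}

#' Masked peak signal-to-noise ratio
#'
#' `10 * log10(R^2 / MSE)` over the masked pixels, with `R` the masked
#' dynamic range of the target. A perfect match returns `Inf` as a
#' sentinel; [evaluate_dataset()] excludes such values from means with a
#' warning.
#'
#' @inheritParams masked_nrmse
#' @return PSNR in dB (possibly `Inf`).
#' @export
masked_psnr <- function(y, y_hat, mask = NULL) {
  sel <- metric_selection(y, y_hat, mask)
  r <- diff(range(sel$y))
  if (r == 0) stop("zero masked dynamic range in the target")
  mse <- mean((sel$y - sel$y_hat)^2)
  if (mse == 0) return(Inf)
  10 * log10(r^2 / mse)
}

#' Masked structural similarity
#'
#' The local SSIM map is computed on the full images (preserving the
#' window context at mask borders) and then averaged over the masked
#' pixels only.
#'
#' @inheritParams masked_nrmse
#' @param params a [scop_params()] carrying the SSIM window settings.
#' @return Mean SSIM over the mask, in `[-1, 1]`.
#' @export
masked_ssim <- function(y, y_hat, mask = NULL, params = scop_params()) {
  sel <- metric_selection(y, y_hat, mask)  # validation only
  s <- ssim_map(y, y_hat, params)
  if (is.null(mask)) mean(s) else mean(s[mask])
}

metric_selection <- function(y, y_hat, mask) {
  check_image(y, "y"); check_image(y_hat, "y_hat")
  check_same_shape(y, y_hat)
  if (is.null(mask)) return(list(y = as.vector(y), y_hat = as.vector(y_hat)))
  check_same_shape(y, mask, "y and mask")
  if (!any(mask)) stop("empty mask")
  list(y = y[mask], y_hat = y_hat[mask])
}

#' Evaluate a restoration test set at full, mitochondria and cristae scope
#'
#' Computes NRMSE, PSNR and SSIM per image at three nested scopes (full
#' frame, mitochondria mask, cristae mask) and aggregates them as mean and
#' standard deviation over the set. Images that fail (e.g. empty masks)
#' are skipped with a warning; infinite PSNR sentinels are excluded from
#' the aggregation with a warning.
#'
#' @param pairs list of `list(pred = , target = )` matrices.
#' @param masks list (same length) of `list(mito = , cristae = )` logical
#'   matrices.
#' @param csv optional path; when given, the per-image table is written as
#'   CSV.
#' @return An object of class `metrics_report`: `per_image` data frame and
#'   `summary` data frame (metric, scope, mean, sd, n).
#' @export
evaluate_dataset <- function(pairs, masks, csv = NULL) {
  stopifnot(length(pairs) == length(masks), length(pairs) >= 1)
  rows <- list()
  for (i in seq_along(pairs)) {
    row <- tryCatch({
      p <- pairs[[i]]; m <- masks[[i]]
      scopes <- list(full = NULL, mito = m$mito, cristae = m$cristae)
      vals <- lapply(scopes, function(msk) {
        c(nrmse = masked_nrmse(p$target, p$pred, msk),
          psnr = masked_psnr(p$target, p$pred, msk),
          ssim = masked_ssim(p$target, p$pred, msk))
      })
      data.frame(image = i, t(unlist(vals)))
    }, error = function(e) {
      warning("image ", i, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no evaluable images")
  per_image <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_image), "image")
  if (any(is.infinite(as.matrix(per_image[metric_cols]))))
    warning("infinite PSNR sentinel(s) excluded from the aggregation")
  summ <- do.call(rbind, lapply(metric_cols, function(cn) {
    v <- per_image[[cn]]
    v <- v[is.finite(v)]
    parts <- strsplit(cn, ".", fixed = TRUE)[[1]]
    data.frame(scope = parts[1], metric = parts[2],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               n = length(v))
  }))
  if (!is.null(csv)) write.csv(per_image, csv, row.names = FALSE)
  structure(list(per_image = per_image, summary = summ),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Restoration metrics over", nrow(x$per_image), "image(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

new_line_profile <- function(position_px, intensity, pixel_size) {
  df <- data.frame(position_px = position_px,
                   position_nm = position_px * pixel_size,
                   intensity = intensity)
  attr(df, "pixel_size") <- pixel_size
  class(df) <- c("line_profile", "data.frame")
  df
}

#' Intensity profile along a straight segment
#'
#' Samples the image by bilinear interpolation at `step`-px intervals along
#' the segment from `from` to `to` (0-based `(row, col)` coordinates,
#' pixel centers at integers).
#'
#' @param image numeric matrix.
#' @param from,to numeric `(row, col)` endpoints, 0-based.
#' @param pixel_size physical pixel size in nm/px.
#' @param step sampling step along the segment (px).
#' @return A `line_profile` data frame with columns `position_px`,
#'   `position_nm`, `intensity`.
#' @export
line_profile <- function(image, from, to, pixel_size = 25, step = 0.25) {
  check_image(image)
  len <- sqrt(sum((to - from)^2))
  if (len <= 0) stop("segment has zero length")
  s <- seq(0, len, by = step)
  r <- from[1] + (to[1] - from[1]) * s / len
  c <- from[2] + (to[2] - from[2]) * s / len
  new_line_profile(s, interp_bilinear(image, r, c), pixel_size)
}

check_profile <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("position_px", "intensity") %in% names(profile)))
  if (nrow(profile) < 5) stop("profile needs at least 5 samples")
  if (any(diff(profile$position_px) <= 0))
    stop("profile positions must be strictly increasing")
  invisible(profile)
}

#' Measure a structure width by Gaussian FWHM fit
#'
#' Least-squares fit of `amplitude * exp(-(x - center)^2 / (2 sigma^2)) +
#' baseline` to a single-peaked line profile; the full width at half
#' maximum is `2 sqrt(2 ln 2) * sigma * pixel_size`, reported in nm.
#' Profiles without a measurable peak (flat, negative amplitude, or
#' non-convergent fits) raise an error rather than returning a number, so
#' unmeasurable structures can be dropped explicitly.
#'
#' @param profile a [line_profile()] (or data frame with `position_px` and
#'   `intensity`).
#' @param pixel_size nm/px; defaults to the profile's own pixel size.
#' @return An object of class `gaussian_fit` with `amplitude`, `center`
#'   (px), `sigma` (px), `baseline`, `fwhm_nm` and `rms_residual`.
#' @export
fwhm_width <- function(profile, pixel_size = NULL) {
  check_profile(profile)
  if (is.null(pixel_size)) pixel_size <- attr(profile, "pixel_size")
  if (is.null(pixel_size)) stop("pixel_size required")
  x <- profile$position_px
  v <- profile$intensity
  if (diff(range(v)) == 0) stop("flat profile: no measurable peak")
  b0 <- min(v)
  a0 <- max(v) - b0
  c0 <- x[which.max(v)]
  above <- x[v >= b0 + a0 / 2]
  s0 <- max(diff(range(above)) / 2.3548, diff(range(x)) / 50)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ a * exp(-(x - cc)^2 / (2 * s^2)) + b,
                      start = list(a = a0, cc = c0, s = s0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit failed: ", conditionMessage(e),
                             call. = FALSE))
  cf <- coef(fit)
  if (cf[["a"]] <= 0) stop("non-positive fitted amplitude: no peak")
  sig <- abs(cf[["s"]])
  if (sig <= 0) stop("degenerate fitted width")
  structure(list(amplitude = cf[["a"]], center = cf[["cc"]], sigma = sig,
                 baseline = cf[["b"]],
                 fwhm_nm = 2 * sqrt(2 * log(2)) * sig * pixel_size,
                 rms_residual = sqrt(mean(stats::residuals(fit)^2))),
            class = "gaussian_fit")
}

find_peaks <- function(v, min_prominence) {
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  keep <- vapply(idx, function(i) {
    h <- v[i]
    left <- v[seq_len(i - 1)]
    higher_l <- which(left > h)
    lmin <- min(left[seq.int(from = if (length(higher_l)) max(higher_l) else 1,
                             to = i - 1)])
    right <- v[(i + 1):n]
    higher_r <- which(right > h)
    rmin <- min(right[seq.int(from = 1,
                              to = if (length(higher_r)) min(higher_r)
                                   else length(right))])
    (h - max(lmin, rmin)) >= min_prominence
  }, logical(1))
  idx[keep]
}

#' Peak-to-peak intervals along a line profile
#'
#' Detects local maxima whose prominence reaches `prominence` times the
#' profile's dynamic range and returns the distances between consecutive
#' peaks in nm (the crista-to-crista interval statistic). Fewer than two
#' peaks give an empty result.
#'
#' @param profile a [line_profile()].
#' @param prominence relative prominence threshold (fraction of the
#'   profile's dynamic range, default 0.1).
#' @param pixel_size nm/px; defaults to the profile's own pixel size.
#' @return Numeric vector of consecutive-peak distances (nm).
#' @export
peak_to_peak_intervals <- function(profile, prominence = 0.1,
                                   pixel_size = NULL) {
  check_profile(profile)
  if (is.null(pixel_size)) pixel_size <- attr(profile, "pixel_size")
  if (is.null(pixel_size)) stop("pixel_size required")
  v <- profile$intensity
  rng <- diff(range(v))
  if (rng == 0) return(numeric(0))
  idx <- find_peaks(v, prominence * rng)
  if (length(idx) < 2) return(numeric(0))
  diff(profile$position_px[idx]) * pixel_size
}
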