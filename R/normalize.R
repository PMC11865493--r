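#' Percentile normalization parameters
#'
#' @param p_low,p_high percentiles in `[0, 100]` with `p_low < p_high`;
#'   defaults 2 and 99.8.
#' @return An object of class `normalization_params`.
#' @export
normalization_params <- function(p_low = 2, p_high = 99.8) {
  if (!(p_low >= 0 && p_low < p_high && p_high <= 100))
    stop("need 0 <= p_low < p_high <= 100")
  structure(list(p_low = p_low, p_high = p_high),
            class = "normalization_params")
}

#' Percentile normalization
#'
#' Maps an image to `(I - perc(I, p_low)) / (perc(I, p_high) -
#' perc(I, p_low))`. Values outside `[0, 1]` (outliers beyond the
#' percentiles) are kept, not clipped. The map is invariant to affine
#' transforms `a * I + b` with `a > 0` of the input, and it is a fixed point
#' on images whose two percentiles are already 0 and 1.
#'
#' @param image numeric matrix.
#' @param params a [normalization_params()].
#' @return Normalized matrix.
#' @export
percentile_normalize <- function(image, params = normalization_params()) {
  check_image(image)
  stopifnot(inherits(params, "normalization_params"))
  q <- quantile(image, c(params$p_low, params$p_high) / 100, names = FALSE)
  if (q[2] <= q[1])
    stop("degenerate percentiles (constant or near-constant image)")
  (image - q[1]) / (q[2] - q[1])
}

#' Anscombe variance-stabilizing transform
#'
#' `I_Ansc = 2 * sqrt(3/8 + I)`, pixel-wise. For Poisson counts with rate
#' >= ~10 the transformed noise is approximately Gaussian with unit
#' variance, which turns Poisson-Gaussian noise into (approximately) white
#' Gaussian noise ahead of Z-score thresholding.
#'
#' @param image numeric matrix with all values >= -3/8.
#' @return Transformed matrix.
#' @export
anscombe_transform <- function(image) {
  check_image(image)
  if (any(image < -3 / 8))
    stop("Anscombe transform undefined for values below -3/8")
  2 * sqrt(3 / 8 + image)
}

#' Robust noise statistics from pseudo-residuals
#'
#' Estimates the Gaussian noise mean as the image median (background pixels
#' dominate) and the noise sd from the Median Absolute Deviation of
#' pseudo-residuals `r(i,j) = (2 I(i,j) - I(i+1,j) - I(i,j+1)) / sqrt(6)`,
#' i.e. `sigma_hat = 1.4826 * median(|r|)`. The residual grid is
#' `(W-1) x (L-1)`: forward offsets falling outside the image are skipped.
#'
#' @param image_ansc numeric matrix, at least 2 x 2 (typically
#'   Anscombe-transformed).
#' @return An object of class `noise_stats` with `mu_hat` and `sigma_hat`.
#' @export
estimate_noise_stats <- function(image_ansc) {
  check_image(image_ansc)
  h <- nrow(image_ansc); w <- ncol(image_ansc)
  if (h < 2 || w < 2) stop("image must be at least 2 x 2")
  core <- image_ansc[1:(h - 1), 1:(w - 1)]
  down <- image_ansc[2:h, 1:(w - 1)]
  right <- image_ansc[1:(h - 1), 2:w]
  r <- (2 * core - down - right) / sqrt(6)
  structure(list(mu_hat = median(image_ansc),
                 sigma_hat = 1.4826 * median(abs(r))),
            class = "noise_stats")
}

#' Z-score map
#'
#' `Z = (I_Ansc - mu_hat) / sigma_hat` with the robust noise statistics of
#' [estimate_noise_stats()].
#'
#' @param image_ansc numeric matrix.
#' @param stats a `noise_stats` object with `sigma_hat > 0`.
#' @return Z-score matrix.
#' @export
zscore_map <- function(image_ansc, stats) {
  check_image(image_ansc)
  stopifnot(inherits(stats, "noise_stats"))
  if (stats$sigma_hat <= 0)
    stop("sigma_hat must be > 0 (degenerate image)")
  (image_ansc - stats$mu_hat) / stats$sigma_hat
}
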