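#' Parameters of the HR -> LR degradation model
#'
#' The synthetic low-resolution inputs are produced by Gaussian blurring
#' (approximating the microscope PSF) followed by Poisson-Gaussian noise.
#' Defaults reproduce the training-set synthesis conditions:
#' `sigma_blur = 3.25` px and `sigma_noise = 4.0` intensity units, matched
#' to images whose foreground maxima lie between 56 and 356.
#'
#' @param sigma_blur Gaussian blur standard deviation (px), >= 0.
#' @param sigma_noise sd of the additive zero-mean Gaussian component
#'   (intensity units), >= 0.
#' @param seed integer seed for the noise draw.
#' @return An object of class `degradation_params`.
#' @export
degradation_params <- function(sigma_blur = 3.25, sigma_noise = 4.0,
                               seed = NULL) {
  if (sigma_blur < 0) stop("sigma_blur must be >= 0")
  if (sigma_noise < 0) stop("sigma_noise must be >= 0")
  structure(list(sigma_blur = sigma_blur, sigma_noise = sigma_noise,
                 seed = seed),
            class = "degradation_params")
}

#' Isotropic Gaussian blur
#'
#' Separable convolution with a normalized Gaussian kernel (radius 4 sigma),
#' reflective boundary handling. `sigma_blur = 0` is the identity.
#'
#' @param image numeric matrix.
#' @param sigma_blur kernel standard deviation in px, >= 0.
#' @return Blurred matrix on the same grid.
#' @export
gaussian_blur <- function(image, sigma_blur) {
  check_image(image)
  if (sigma_blur < 0) stop("sigma_blur must be >= 0")
  .gauss_blur_cpp(image, sigma_blur)
}

#' Add Poisson-Gaussian noise
#'
#' Each pixel value is interpreted directly as the expected photon count
#' (gain 1): the output is `Poisson(pixel) + N(0, sigma_noise^2)`, with no
#' clipping, so the flat-field variance model is `mean + sigma_noise^2`.
#'
#' @param image non-negative numeric matrix.
#' @param sigma_noise sd of the additive Gaussian component.
#' @param seed integer seed; identical seeds give identical outputs.
#' @return Noisy float matrix.
#' @export
add_poisson_gaussian_noise <- function(image, sigma_noise, seed = NULL) {
  check_image(image)
  if (any(image < 0))
    stop("image must be non-negative (Poisson intensity undefined)")
  if (sigma_noise < 0) stop("sigma_noise must be >= 0")
  with_seed(seed, {
    n <- length(image)
    noisy <- rpois(n, lambda = as.vector(image)) +
      if (sigma_noise > 0) rnorm(n, 0, sigma_noise) else 0
    matrix(noisy, nrow(image), ncol(image))
  })
}

#' Synthesize a low-resolution input from a high-resolution image
#'
#' Blur first, then noise; this order is fixed. `sigma_noise = 0` disables
#' the stochastic stage entirely (the parameter is the single noise knob, so
#' zero means a noise-free degradation and `degrade` becomes deterministic);
#' with both parameters zero the input is returned unchanged.
#'
#' @param image non-negative numeric matrix.
#' @param params a [degradation_params()].
#' @return Degraded matrix.
#' @export
degrade <- function(image, params) {
  stopifnot(inherits(params, "degradation_params"))
  blurred <- gaussian_blur(image, params$sigma_blur)
  # blur of a non-negative image stays >= 0 up to rounding
  blurred[blurred < 0] <- 0
  if (params$sigma_noise == 0) return(blurred)
  add_poisson_gaussian_noise(blurred, params$sigma_noise, params$seed)
}

#' Richardson-Lucy deconvolution with a Gaussian PSF
#'
#' Standard multiplicative iterations, used to sharpen cristae ridges in the
#' training targets. Non-negativity is preserved; `psf_sigma = 0` returns
#' the input unchanged (delta PSF fixed point).
#'
#' @param image non-negative numeric matrix with positive total intensity.
#' @param psf_sigma Gaussian PSF standard deviation (px).
#' @param n_iter number of iterations (>= 1).
#' @return Enhanced matrix.
#' @export
richardson_lucy_enhance <- function(image, psf_sigma = 1.5, n_iter = 10) {
  check_image(image)
  if (any(image < 0)) stop("image must be non-negative")
  if (sum(image) == 0) stop("image has zero total intensity")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (psf_sigma <= 0) return(image)
  est <- image
  eps <- 1e-12
  for (k in seq_len(n_iter)) {
    conv_est <- .gauss_blur_cpp(est, psf_sigma)
    ratio <- image / (conv_est + eps)
    est <- est * .gauss_blur_cpp(ratio, psf_sigma)
  }
  est
}

#' Rescale an image so mitochondria match the training width
#'
#' Inference inputs are resampled isotropically by
#' `factor = target_width / measured_width` so that their average
#' mitochondrial width matches the width the model was trained on
#' (15.64 px, i.e. 391 nm at 25 nm/px). Intensities use Catmull-Rom
#' (cubic) interpolation; use [rescale_mask()] for binary masks.
#'
#' @param image numeric matrix.
#' @param measured_width measured mean mitochondrial width in px, > 0.
#' @param target_width training width in px.
#' @return List with `image` (resampled) and `factor`.
#' @export
rescale_to_width <- function(image, measured_width, target_width = 15.64) {
  check_image(image)
  if (measured_width <= 0) stop("measured_width must be > 0")
  factor <- target_width / measured_width
  if (abs(factor - 1) < 1e-12)
    return(list(image = image, factor = 1))
  h2 <- max(1L, as.integer(round(nrow(image) * factor)))
  w2 <- max(1L, as.integer(round(ncol(image) * factor)))
  list(image = .bicubic_resize_cpp(image, h2, w2), factor = factor)
}

#' Convert a width in pixels to physical units
#'
#' Convenience for reporting the training mitochondrial width in nm, e.g.
#' 15.64 px at 25 nm/px is 391 nm.
#'
#' @param width_px width in pixels.
#' @param pixel_size physical pixel size in nm/px.
#' @return Width in nm.
#' @export
width_px_to_nm <- function(width_px, pixel_size) {
  stopifnot(width_px >= 0, pixel_size > 0)
  width_px * pixel_size
}

#' Rescale a binary mask by nearest-neighbour resampling
#'
#' @param mask logical or 0/1 matrix.
#' @param factor isotropic scale factor, > 0.
#' @return Logical matrix.
#' @export
rescale_mask <- function(mask, factor) {
  if (factor <= 0) stop("factor must be > 0")
  h <- nrow(mask); w <- ncol(mask)
  h2 <- max(1L, as.integer(round(h * factor)))
  w2 <- max(1L, as.integer(round(w * factor)))
  ri <- pmin(pmax(round((seq_len(h2) - 0.5) / factor + 0.5), 1), h)
  ci <- pmin(pmax(round((seq_len(w2) - 0.5) / factor + 0.5), 1), w)
  (mask[ri, ci, drop = FALSE]) > 0
}
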