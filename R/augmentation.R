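#' Stochastic augmentation configuration
#'
#' View generation for contrastive pre-training and fine-tuning. Per view
#' the chain is, in fixed order, crop -> horizontal flip -> brightness /
#' contrast -> additive Gaussian noise, so the noise model acts at the
#' final (training) resolution where B-scan noise patterns live. Noise
#' parameters are drawn uniformly per view from `noise_mu_range` (default
#' `[-0.1, 0.15]`) and `noise_var_range` (default `[0, 0.2]`); crops cover
#' 50-100\% of the original scan area at the input aspect ratio; outputs
#' are resized to `output_size` and clipped to `[0, 1]`.
#'
#' @param noise_mu_range interval for the noise mean.
#' @param noise_var_range interval for the noise variance (>= 0).
#' @param crop_area_range interval of crop area fractions, within `(0, 1]`.
#' @param brightness_delta_range interval for the additive brightness delta.
#' @param contrast_factor_range interval for the contrast factor (> 0),
#'   applied as scaling about the image mean.
#' @param hflip_prob probability of a horizontal flip.
#' @param output_size `(height, width)` of emitted views.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(noise_mu_range = c(-0.1, 0.15),
                                noise_var_range = c(0, 0.2),
                                crop_area_range = c(0.5, 1.0),
                                brightness_delta_range = c(-0.2, 0.2),
                                contrast_factor_range = c(0.8, 1.2),
                                hflip_prob = 0.5,
                                output_size = c(224, 224),
                                interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  check_range(noise_mu_range, "noise_mu_range")
  check_range(noise_var_range, "noise_var_range")
  if (noise_var_range[1] < 0) stop_config("noise variance must be >= 0")
  check_range(crop_area_range, "crop_area_range")
  if (crop_area_range[1] <= 0 || crop_area_range[2] > 1)
    stop_config("crop_area_range must lie within (0, 1]")
  check_range(brightness_delta_range, "brightness_delta_range")
  check_range(contrast_factor_range, "contrast_factor_range")
  if (contrast_factor_range[1] <= 0) stop_config("contrast factor must be > 0")
  check_number(hflip_prob, "hflip_prob", 0, 1)
  if (length(output_size) != 2L || any(output_size < 2))
    stop_config("output_size must be (height, width), both >= 2")
  structure(list(noise_mu_range = noise_mu_range,
                 noise_var_range = noise_var_range,
                 crop_area_range = crop_area_range,
                 brightness_delta_range = brightness_delta_range,
                 contrast_factor_range = contrast_factor_range,
                 hflip_prob = hflip_prob,
                 output_size = as.integer(output_size),
                 interpolation = interpolation),
            class = "augmentation_config")
}

# identity configuration: useful for evaluation-time resizing only
identity_augmentation <- function(output_size) {
  augmentation_config(noise_mu_range = c(0, 0), noise_var_range = c(0, 0),
                      crop_area_range = c(1, 1),
                      brightness_delta_range = c(0, 0),
                      contrast_factor_range = c(1, 1), hflip_prob = 0,
                      output_size = output_size)
}

#' Additive Gaussian noise with clipping
#'
#' `clip(image + n, 0, 1)` with `n` i.i.d. normal with mean `mu` and
#' variance `var` per pixel.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param mu noise mean.
#' @param var noise variance (>= 0).
#' @return A matrix in `[0, 1]` of the same shape.
#' @export
add_gaussian_noise <- function(image, mu, var) {
  if (var < 0) stop_domain("noise variance must be >= 0")
  if (var == 0 && mu == 0) return(image)
  n <- matrix(rnorm(length(image), mu, sqrt(var)), nrow(image), ncol(image))
  clip01(image + n)
}

#' Random-position crop at a given area fraction, resized
#'
#' The crop window has area `area_fraction * H * W` at the image's aspect
#' ratio (so each side scales by `sqrt(area_fraction)`), is uniformly
#' positioned, and is resized to `output_size`.
#'
#' @param image numeric matrix.
#' @param area_fraction fraction of the original area in `(0, 1]`.
#' @param output_size `(height, width)` of the output.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return A matrix of size `output_size`.
#' @export
random_crop_resize <- function(image, area_fraction,
                               output_size = c(224, 224),
                               interpolation = "bilinear") {
  if (area_fraction <= 0 || area_fraction > 1)
    stop_domain("area_fraction must lie in (0, 1]")
  H <- nrow(image); W <- ncol(image)
  ch <- round(H * sqrt(area_fraction))
  cw <- round(W * sqrt(area_fraction))
  if (ch < 2 || cw < 2) stop_domain("crop window smaller than 2x2")
  top <- if (ch < H) sample.int(H - ch + 1L, 1L) else 1L
  left <- if (cw < W) sample.int(W - cw + 1L, 1L) else 1L
  win <- image[top:(top + ch - 1L), left:(left + cw - 1L), drop = FALSE]
  method <- if (interpolation == "nearest") 0L else 1L
  resize_image_cpp(win, as.integer(output_size[1]), as.integer(output_size[2]),
                   method)
}

#' Brightness and contrast adjustment
#'
#' `clip(factor * (image - m) + m + delta, 0, 1)` with `m` the image mean:
#' contrast scales about the mean (so constant images are unchanged by it),
#' brightness shifts additively.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param delta additive brightness shift.
#' @param factor contrast factor (> 0).
#' @return A matrix in `[0, 1]`.
#' @export
adjust_brightness_contrast <- function(image, delta, factor) {
  if (factor <= 0) stop_domain("contrast factor must be > 0")
  m <- mean(image)
  clip01(factor * (image - m) + m + delta)
}

#' Horizontal flip (left-right mirror; an involution)
#' @param image numeric matrix.
#' @return The mirrored matrix.
#' @export
hflip <- function(image) image[, rev(seq_len(ncol(image))), drop = FALSE]

#' Draw one augmented view of a B-scan
#'
#' Applies crop -> flip -> brightness/contrast -> noise with parameters
#' drawn uniformly from the configured ranges, using R's RNG stream (seed
#' at the call site for determinism).
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param config an [augmentation_config()].
#' @return A matrix of size `config$output_size` in `[0, 1]`.
#' @export
augment_view <- function(image, config) {
  if (min(image) < 0 || max(image) > 1)
    stop_domain("image intensities must lie in [0, 1]")
  a <- runif(1, config$crop_area_range[1], config$crop_area_range[2])
  out <- random_crop_resize(image, a, config$output_size, config$interpolation)
  out <- clip01(out)
  if (config$hflip_prob > 0 && runif(1) < config$hflip_prob) out <- hflip(out)
  delta <- runif(1, config$brightness_delta_range[1], config$brightness_delta_range[2])
  factor <- runif(1, config$contrast_factor_range[1], config$contrast_factor_range[2])
  out <- adjust_brightness_contrast(out, delta, factor)
  mu <- runif(1, config$noise_mu_range[1], config$noise_mu_range[2])
  v <- runif(1, config$noise_var_range[1], config$noise_var_range[2])
  add_gaussian_noise(out, mu, v)
}
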