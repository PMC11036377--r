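#' Sample random bias-field parameters
#'
#' Coefficients for all 3-variable monomials of total degree <= `order`,
#' each drawn from U\[-max_magnitude, max_magnitude\].
#'
#' @param order polynomial order (default 3).
#' @param max_magnitude coefficient magnitude bound (default 0.5).
#' @return Object of class `bias_params`: list with `order`,
#'   `max_magnitude` and `coefficients` (named by monomial exponents
#'   `"a.b.c"`).
#' @export
sample_bias_field <- function(order = 3, max_magnitude = 0.5) {
  ex <- bias_monomials(order)
  co <- runif(nrow(ex), -max_magnitude, max_magnitude)
  names(co) <- paste(ex[, 1], ex[, 2], ex[, 3], sep = ".")
  structure(list(order = order, max_magnitude = max_magnitude,
                 coefficients = co),
            class = "bias_params")
}

bias_monomials <- function(order) {
  ex <- expand.grid(a = 0:order, b = 0:order, c = 0:order)
  as.matrix(ex[rowSums(ex) <= order, , drop = FALSE])
}

# polynomial over normalized coordinates in [-1, 1]^3
bias_polynomial <- function(params, d) {
  ex <- bias_monomials(params$order)
  xs <- lapply(1:3, function(a)
    if (d[a] > 1) seq(-1, 1, length.out = d[a]) else 0)
  P <- array(0, d)
  X <- array(xs[[1]], d)
  Y <- array(rep(xs[[2]], each = d[1]), d)
  Z <- array(rep(xs[[3]], each = d[1] * d[2]), d)
  for (i in seq_len(nrow(ex)))
    P <- P + params$coefficients[i] * X^ex[i, 1] * Y^ex[i, 2] * Z^ex[i, 3]
  P
}

#' Apply a multiplicative polynomial bias field
#'
#' Simulates smooth intensity inhomogeneity: the image is multiplied by
#' `exp(P(x))` where `P` is the order-3 polynomial over coordinates
#' normalized to `[-1, 1]^3`.  The exponential keeps the field strictly
#' positive.
#'
#' @param image an [mri_image] or 3D array.
#' @param params a `bias_params` object.
#' @return Same type as `image`.
#' @export
apply_bias <- function(image, params) {
  vox <- as_vox_array(image)
  out <- vox * exp(bias_polynomial(params, dim(vox)))
  if (inherits(image, "mri_image")) mri_image(out, image$voxel_size) else out
}

#' Sample random noise parameters
#'
#' Zero-mean Gaussian noise with standard deviation drawn from
#' U\[5e-3, 0.1\].
#'
#' @return Object of class `noise_params`: list with `mean` (0) and `std`.
#' @export
sample_noise <- function() {
  structure(list(mean = 0, std = runif(1, 5e-3, 0.1)),
            class = "noise_params")
}

#' Add Gaussian noise to an image
#'
#' @param image an [mri_image] or 3D array.
#' @param params a `noise_params` object.
#' @return Same type as `image`.
#' @export
apply_noise <- function(image, params) {
  vox <- as_vox_array(image)
  if (params$std > 0)
    vox <- vox + rnorm(length(vox), params$mean, params$std)
  if (inherits(image, "mri_image")) mri_image(vox, image$voxel_size) else vox
}

#' Sample a log-gamma exponent
#'
#' @param max_log_gamma half-width of the uniform sampling interval in log
#'   space (default 0.3, "slight" contrast variations).
#' @return A numeric scalar `log_gamma`.
#' @export
sample_log_gamma <- function(max_log_gamma = 0.3) {
  runif(1, -max_log_gamma, max_log_gamma)
}

#' Apply a gamma contrast perturbation
#'
#' Raises a `[0, 1]`-scaled image to the power `exp(log_gamma)`.  The
#' power function is monotone on `[0, 1]`, so voxel ordering is preserved.
#' Images with negative values are rejected; normalize first (see
#' [normalize_intensity]).
#'
#' @param image an [mri_image] or 3D array with values in `[0, 1]`.
#' @param log_gamma exponent in log space; `0` is the identity.
#' @return Same type as `image`.
#' @export
apply_gamma <- function(image, log_gamma) {
  vox <- as_vox_array(image)
  if (any(vox < 0))
    stop("apply_gamma requires non-negative intensities; ",
         "rescale with normalize_intensity() first")
  out <- vox^exp(log_gamma)
  if (inherits(image, "mri_image")) mri_image(out, image$voxel_size) else out
}
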