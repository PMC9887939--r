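#' Root-kernel density (Gaussian, biomass-dependent width)
#'
#' Pointwise value of the shrub's root-zone kernel: a Gaussian whose width
#' `S(B) = SG1 * (1 + E1 * B)` grows with the aboveground biomass at the
#' shoot location (root augmentation), while the prefactor keeps the
#' seedling normalization. Its integral over the plane is `(1 + E1 * B)^2`,
#' so a bigger shoot taps proportionally more water.
#'
#' @param r distance, m (`>= 0`).
#' @param B aboveground biomass at the shoot location, kg/m^2 (`>= 0`).
#' @param params a [veg_params] object (uses `SG1`, `E1`).
#' @param dim spatial dimension, 1 or 2. The 1D analogue keeps the same
#'   defining property: total mass `(1 + E1 * B)^2`.
#' @return Kernel density, 1/m^2 (1/m in 1D).
#' @export
root_kernel_value <- function(r, B, params, dim = 2) {
  if (any(r < 0)) stop("distance r must be >= 0")
  if (any(B < 0)) stop("biomass B must be >= 0")
  S <- params$SG1 * (1 + params$E1 * B)
  if (dim == 2) {
    1 / (2 * pi * params$SG1^2) * exp(-r^2 / (2 * S^2))
  } else {
    (1 + params$E1 * B)^2 / (sqrt(2 * pi) * S) * exp(-r^2 / (2 * S^2))
  }
}

#' Sucker/dispersal kernel density (fat-tailed)
#'
#' Cauchy-type kernel for the distribution of potential root suckers (shrub)
#' or dispersed seeds (sedge). Unit mass; tails decay algebraically, much
#' heavier than a Gaussian, which is what permits sprouting well beyond the
#' parent's depleted halo.
#'
#' @param r distance, m (`>= 0`).
#' @param SD kernel width, m (`> 0`).
#' @param dim spatial dimension, 1 or 2.
#' @return Kernel density, 1/m^2 (1/m in 1D).
#' @export
sucker_kernel_value <- function(r, SD, dim = 2) {
  if (any(r < 0)) stop("distance r must be >= 0")
  if (!is.numeric(SD) || any(SD <= 0)) stop("kernel width SD must be > 0")
  if (dim == 2) {
    SD / (2 * pi * (r^2 + SD^2)^(3 / 2))
  } else {
    SD / (pi * (r^2 + SD^2))
  }
}

# Fourier transforms of the kernels (isotropic, as functions of |k|).
# Gaussian of width S carrying mass m: m * exp(-S^2 k^2 / 2).
# Cauchy-type of width SD: exp(-SD * |k|) in both 1D and 2D.
kernel_hat_gaussian <- function(kmag, S, mass = 1) mass * exp(-0.5 * S^2 * kmag^2)
kernel_hat_sucker <- function(kmag, SD) exp(-SD * kmag)

# Periodic FFT convolution of a real field with a kernel given by its
# (real, symmetric) transfer function sampled on the grid.
fft_conv <- function(field, khat) {
  Re(fft(fft(field) * khat, inverse = TRUE)) / length(field)
}
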