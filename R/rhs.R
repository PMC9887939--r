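#' Local sedge growth and uptake rates
#'
#' The sedge's roots are laterally confined, so its nonlocal terms collapse
#' to the algebraic local limit:
#' growth `Lam2 * W * (1 + E2*B2)^2` and uptake `Gam2 * B2 * (1 + E2*B2)^2`.
#'
#' @param B2 sedge biomass field, kg/m^2.
#' @param W soil-water field, kg/m^2.
#' @param params a [veg_params].
#' @return A list with fields `growth` (1/y) and `uptake` (multiplies `W` in
#'   the water balance).
#' @export
local_rates_cyperus <- function(B2, W, params) {
  if (!identical(dim(B2), dim(W)) && !identical(length(B2), length(W)))
    stop("B2 and W must have the same shape")
  fac <- (1 + params$E2 * B2)^2
  list(growth = params$Lam2 * W * fac,
       uptake = params$Gam2 * B2 * fac)
}

#' Biomass-dependent evaporation rate
#'
#' `L = N * (1 - R1*B1/K1 - R2*B2/K2)`: evaporation is `N` on bare soil and
#' is reduced by canopy shading, bounded below by `N*(1 - R1 - R2) > 0`.
#'
#' @param B1,B2 biomass fields, kg/m^2.
#' @param params a [veg_params].
#' @return Evaporation-rate field, 1/y.
#' @export
evaporation_rate <- function(B1, B2, params) {
  params$N * (1 - params$R1 * B1 / params$K1 - params$R2 * B2 / params$K2)
}

#' Nonlocal sucker / dispersal growth term
#'
#' Biomass gained at each point from root suckers (species 1) or dispersed
#' seeds (species 2) of plants elsewhere, gated by local water availability:
#' `D_i = Th_i * W/(W + Wstar_i) * (Phi_i * B_i)` with `Phi_i` the unit-mass
#' fat-tailed kernel and `*` periodic convolution.
#'
#' @param Bi biomass field of the sprouting species, kg/m^2.
#' @param W soil-water field, kg/m^2 (must be nonnegative).
#' @param species 1 (shrub, width `SD1`) or 2 (sedge, width `SD2`).
#' @param params a [veg_params].
#' @param approx a [build_kernel_approx] result (holds the kernel transforms).
#' @return Field of biomass gain rate, kg/m^2/y.
#' @export
sucker_growth <- function(Bi, W, species, params, approx) {
  if (any(W < 0)) stop("soil-water field must be >= 0")
  stopifnot(species %in% c(1, 2))
  if (species == 1) {
    params$Th1 * (W / (W + params$Wstar1)) * fft_conv(Bi, approx$Ks1)
  } else {
    params$Th2 * (W / (W + params$Wstar2)) * fft_conv(Bi, approx$Ks2)
  }
}

#' Full model right-hand side (reference R implementation)
#'
#' Assembles the time derivatives of the three fields:
#' `dB_i/dT = G_B_i * B_i * (1 - B_i/K_i) - M_i*B_i + D_i`, and
#' `dW/dT = P - L*W - W*(G_W_1 + G_W_2) + DW * Laplacian(W)`,
#' with the shrub's growth/uptake evaluated through the fixed-width kernel
#' approximation and the Laplacian applied spectrally. This pure-R path is
#' the reference the compiled solver core is tested against.
#'
#' @param state a [veg_state].
#' @param params a [veg_params].
#' @param grid the [veg_grid].
#' @param approx a [build_kernel_approx] result for `params` on `grid`.
#' @return A list `dB1, dB2, dW` of derivative fields (kg/m^2/y).
#' @export
veg_rhs <- function(state, params, grid, approx) {
  B1 <- state$B1; B2 <- state$B2; W <- state$W
  Gb1 <- nonlocal_growth(W, B1, approx, params)
  Gw1 <- nonlocal_uptake(B1, approx, params)
  loc <- local_rates_cyperus(B2, W, params)
  D1 <- sucker_growth(B1, W, 1, params, approx)
  D2 <- sucker_growth(B2, W, 2, params, approx)
  L <- evaporation_rate(B1, B2, params)
  lapW <- params$DW * fft_conv(W, approx$lap)
  out <- list(
    dB1 = Gb1 * B1 * (1 - B1 / params$K1) - params$M1 * B1 + D1,
    dB2 = loc$growth * B2 * (1 - B2 / params$K2) - params$M2 * B2 + D2,
    dW = params$P - L * W - W * (Gw1 + loc$uptake) + lapW)
  for (nm in names(out)) {
    if (!all(is.finite(out[[nm]])))
      stop("non-finite values in rhs term ", nm,
           " (mean B1 = ", mean(B1), ", mean B2 = ", mean(B2),
           ", mean W = ", mean(W), ")")
  }
  out
}
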