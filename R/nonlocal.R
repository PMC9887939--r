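#' Nonlocal shrub growth rate
#'
#' Growth rate of species 1 at each point: soil water gathered through the
#' root kernel centred at the *shoot* location, whose width is set by the
#' biomass there,
#' `G_B(x) = Lam1 * sum_j w_j(B1(x)) * (G_j * W)(x)`
#' with `G_j` the fixed-width kernels of the approximation and `*` periodic
#' convolution.
#'
#' @param W soil-water field, kg/m^2.
#' @param B1 shrub biomass field, kg/m^2.
#' @param approx a [build_kernel_approx] result on the same grid.
#' @param params a [veg_params].
#' @return Growth-rate field, 1/y.
#' @export
nonlocal_growth <- function(W, B1, approx, params) {
  stopifnot(identical(dim(W), dim(B1)))
  w <- kernel_weights(B1, approx)
  out <- matrix(0, nrow(W), ncol(W))
  for (j in seq_len(approx$J)) {
    conv <- fft_conv(W, approx$Kroot[, , j])
    out <- out + matrix(w[, j], nrow(W), ncol(W)) * conv
  }
  params$Lam1 * out
}

#' Nonlocal shrub water uptake
#'
#' Uptake rate density at each point: water drawn *from* `x` by all plants
#' whose root zones reach it; the kernel width is set by the biomass at the
#' *plant* location (transposed kernel arguments relative to the growth
#' term — this asymmetry is what digs bare-soil halos around large shrubs),
#' `G_W(x) = Gam1 * sum_j (G_j * [w_j(B1) B1])(x)`.
#' The result multiplies `W` in the water balance.
#'
#' @inheritParams nonlocal_growth
#' @return Uptake field, (m^2/kg... per-unit-water) 1/y after multiplying by W.
#' @export
nonlocal_uptake <- function(B1, approx, params) {
  w <- kernel_weights(B1, approx)
  out <- matrix(0, nrow(B1), ncol(B1))
  for (j in seq_len(approx$J)) {
    src <- matrix(w[, j], nrow(B1), ncol(B1)) * B1
    out <- out + fft_conv(src, approx$Kroot[, , j])
  }
  params$Gam1 * out
}

#' Brute-force quadrature oracles for the nonlocal terms
#'
#' Direct double-sum quadrature of the defining integrals with the exact
#' biomass-dependent Gaussian kernel, periodized by summing over the 3x3
#' block of neighbour images (the wrapped kernel the periodic convolution
#' sees). O(n^4) in 2D — refuses grids above 96 x 96. Testing only.
#'
#' @inheritParams nonlocal_growth
#' @param grid the [veg_grid] the fields live on.
#' @return The growth (1/y) or uptake field.
#' @export
brute_force_growth <- function(W, B1, grid, params) {
  guard_brute_force(grid)
  pw <- periodized_pairs(grid)
  n <- length(W)
  out <- numeric(n)
  B1v <- as.vector(B1); Wv <- as.vector(W)
  for (i in seq_len(n)) {
    kv <- periodized_kernel_row(pw, i, B1v[i], params)
    out[i] <- sum(kv * Wv) * grid$dA
  }
  matrix(params$Lam1 * out, grid$nx, grid$ny)
}

#' @rdname brute_force_growth
#' @export
brute_force_uptake <- function(B1, grid, params) {
  guard_brute_force(grid)
  pw <- periodized_pairs(grid)
  n <- length(B1)
  out <- numeric(n)
  B1v <- as.vector(B1)
  for (i in seq_len(n)) {
    # kernel width at the plant location x' (the source point)
    kv <- periodized_kernel_row(pw, i, B1v, params)
    out[i] <- sum(kv * B1v) * grid$dA
  }
  matrix(params$Gam1 * out, grid$nx, grid$ny)
}

guard_brute_force <- function(grid) {
  if (grid$nx * grid$ny > 96 * 96)
    stop("brute-force quadrature refused on grids larger than 96 x 96")
  invisible(TRUE)
}

# coordinate differences and image shifts shared by the oracle rows
periodized_pairs <- function(grid) {
  xs <- rep(grid$x, times = grid$ny)
  ys <- rep(grid$y, each = grid$nx)
  shifts <- if (is_1d(grid)) {
    cbind(sx = c(-grid$Lx, 0, grid$Lx), sy = 0)
  } else {
    as.matrix(expand.grid(sx = c(-grid$Lx, 0, grid$Lx),
                          sy = c(-grid$Ly, 0, grid$Ly)))
  }
  list(xs = xs, ys = ys, shifts = shifts, Lx = grid$Lx, Ly = grid$Ly,
       dim = if (is_1d(grid)) 1 else 2)
}

# row i of the periodized kernel matrix; B is the biomass setting the width
# (scalar for the growth term, the full source vector for the uptake term).
# Differences are wrapped to the nearest image first so the +-1 image block
# covers (-1.5L, 1.5L] symmetrically about every target point.
periodized_kernel_row <- function(pw, i, B, params) {
  wrap <- function(d, L) d - L * round(d / L)
  dx0 <- wrap(pw$xs - pw$xs[i], pw$Lx)
  dy0 <- if (pw$dim == 1) 0 else wrap(pw$ys - pw$ys[i], pw$Ly)
  kv <- 0
  for (s in seq_len(nrow(pw$shifts))) {
    r <- sqrt((dx0 + pw$shifts[s, 1])^2 + (dy0 + pw$shifts[s, 2])^2)
    kv <- kv + root_kernel_value(r, B, params, dim = pw$dim)
  }
  kv
}
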