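#' Periodic computational grid
#'
#' A periodic (in all directions) rectangular grid. Set `ny = 1` for a 1D
#' domain. Grid spacings are `dx = Lx/nx`, `dy = Ly/ny`; cell centres sit at
#' `(i - 1) * dx` so the origin is a grid point.
#'
#' @param Lx,Ly domain lengths, m. `Ly` defaults to `Lx` (ignored when
#'   `ny = 1`, where it is set to `dy = dx` for a unit-depth 1D strip).
#' @param nx,ny number of grid points per direction (powers of two
#'   recommended for FFT speed; any size works).
#' @return An object of class `veg_grid` with fields `Lx, Ly, nx, ny, dx, dy,
#'   x, y, kx, ky, k2, kmag, dA`.
#' @export
#' @examples
#' g <- veg_grid(50, 128)        # 2D, 50 m x 50 m
#' g1 <- veg_grid(200, 1024, ny = 1)  # 1D transect
veg_grid <- function(Lx, nx, Ly = Lx, ny = nx) {
  stopifnot(Lx > 0, nx >= 2, ny >= 1)
  if (ny == 1L) Ly <- Lx / nx  # unit-depth strip: dy = dx
  dx <- Lx / nx
  dy <- Ly / ny
  kx <- fft_freq(nx, Lx)
  ky <- if (ny == 1L) 0 else fft_freq(ny, Ly)
  k2 <- outer(kx^2, rep(1, ny)) + outer(rep(1, nx), ky^2)
  g <- list(Lx = Lx, Ly = Ly, nx = as.integer(nx), ny = as.integer(ny),
            dx = dx, dy = dy,
            x = (seq_len(nx) - 1) * dx, y = (seq_len(ny) - 1) * dy,
            kx = kx, ky = ky, k2 = k2, kmag = sqrt(k2), dA = dx * dy)
  class(g) <- "veg_grid"
  g
}

#' Angular FFT frequencies
#'
#' Wavenumbers `2*pi*m/L` in standard FFT output order.
#'
#' @param n number of samples.
#' @param L domain length.
#' @return Numeric vector of length `n`.
#' @export
fft_freq <- function(n, L) {
  m <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  2 * pi * m / L
}

#' @export
print.veg_grid <- function(x, ...) {
  if (x$ny == 1L) {
    cat(sprintf("<veg_grid 1D> L = %g m, n = %d, dx = %g m\n", x$Lx, x$nx, x$dx))
  } else {
    cat(sprintf("<veg_grid 2D> %g m x %g m, %d x %d, dx = %g m\n",
                x$Lx, x$Ly, x$nx, x$ny, x$dx))
  }
  invisible(x)
}

is_1d <- function(grid) grid$ny == 1L

# Does the grid resolve the narrowest active Gaussian root kernel? Spectral
# evaluation needs roughly dx <= SG1 (so exp(-SG1^2 k_max^2 / 2) is small at
# the Nyquist wavenumber); widths below the grid scale fall back smoothly to
# the exact local limit (transfer function ~ mass at all resolved k), which
# is the intended behaviour for near-local presets.
resolves_kernel <- function(grid, params) {
  grid$dx <= params$SG1 || params$SG1 < grid$dx / 4
}
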