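#' System state
#'
#' Holds the three model fields on a grid: shrub biomass `B1`, sedge biomass
#' `B2`, and soil-water content `W`, all in kg/m^2, plus the current time `T`
#' in years. Fields are `nx x ny` matrices (`ny = 1` in 1D).
#'
#' @param B1,B2,W fields (matrices or vectors coerced to `nx x 1`).
#' @param T time, y.
#' @param grid a [veg_grid]; used to check shapes.
#' @return An object of class `veg_state`.
#' @export
veg_state <- function(B1, B2, W, T = 0, grid = NULL) {
  as_field <- function(f) {
    if (is.null(dim(f))) f <- matrix(f, ncol = 1)
    storage.mode(f) <- "double"
    f
  }
  s <- list(B1 = as_field(B1), B2 = as_field(B2), W = as_field(W), T = T)
  if (!identical(dim(s$B1), dim(s$B2)) || !identical(dim(s$B1), dim(s$W)))
    stop("fields B1, B2, W must have identical shapes")
  if (!is.null(grid) &&
      !identical(dim(s$B1), c(grid$nx, grid$ny)))
    stop("field shape does not match grid (", grid$nx, " x ", grid$ny, ")")
  for (nm in c("B1", "B2", "W")) {
    if (!all(is.finite(s[[nm]]))) stop("field ", nm, " contains non-finite values")
    if (any(s[[nm]] < 0)) stop("field ", nm, " contains negative values")
  }
  class(s) <- "veg_state"
  s
}

#' Spatially uniform state
#'
#' @param grid a [veg_grid].
#' @param B1,B2,W scalar field values, kg/m^2.
#' @param T time, y.
#' @return A [veg_state] with constant fields.
#' @export
uniform_state <- function(grid, B1, B2, W, T = 0) {
  m <- function(v) matrix(v, grid$nx, grid$ny)
  veg_state(m(B1), m(B2), m(W), T = T, grid = grid)
}

#' @export
print.veg_state <- function(x, ...) {
  d <- dim(x$B1)
  cat(sprintf("<veg_state> %d x %d at T = %g y\n", d[1], d[2], x$T))
  cat(sprintf("  mean B1 = %.4g, mean B2 = %.4g, mean W = %.4g kg/m^2\n",
              mean(x$B1), mean(x$B2), mean(x$W)))
  invisible(x)
}

state_means <- function(state) {
  c(B1 = mean(state$B1), B2 = mean(state$B2), W = mean(state$W))
}
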