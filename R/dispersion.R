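#' Default wavenumber grid for stability analysis
#'
#' Spans the scales the root and sucker kernels can act on: the Turing mode
#' sits near `1/S(B)`, so the grid extends to a few times `1/SG1`.
#'
#' @param params a [veg_params].
#' @param n number of wavenumbers.
#' @return Increasing vector of strictly positive wavenumbers, 1/m.
#' @export
default_k_grid <- function(params, n = 120) {
  kmax <- max(4, 6 / params$SG1)
  seq(0.05, kmax, length.out = n)
}

#' Dispersion relation about a uniform state
#'
#' Growth rates `sigma(k)` of spatial Fourier-mode perturbations
#' `(b1, b2, w) * cos(k x)` about a uniform equilibrium. The 3x3 linear
#' operator at each `k` is built numerically by central finite differences
#' of the discretized right-hand side along single-mode perturbations on a
#' dedicated one-wavelength 1D grid (this sidesteps the error-prone algebra
#' of differentiating the biomass-dependent kernel width, and is exactly
#' testable at `k = 0` and about bare soil). `k = 0` entries use a uniform
#' perturbation and must reproduce the uniform Jacobian.
#'
#' @param eq a `uniform_equilibrium` (or list with `B1, B2, W`).
#' @param params a [veg_params].
#' @param k_grid wavenumbers, 1/m (`>= 0`).
#' @param n_mode grid points per wavelength for the mode construction.
#' @param J kernel-approximation order.
#' @return A `dispersion_curve`: list with `k`, `sigma` (3 x nk complex
#'   matrix, all eigenvalues), and `lambda` (per-k max real part).
#' @export
dispersion_relation <- function(eq, params, k_grid = default_k_grid(params),
                                n_mode = 32, J = 5) {
  base <- c(eq$B1, eq$B2, eq$W)
  nk <- length(k_grid)
  sigma <- matrix(NA_complex_, 3, nk)
  for (i in seq_len(nk)) {
    M <- mode_operator(base, params, k_grid[i], n_mode, J)
    sigma[, i] <- eigen(M, only.values = TRUE)$values
  }
  out <- list(k = k_grid, sigma = sigma, lambda = apply(Re(sigma), 2, max))
  class(out) <- "dispersion_curve"
  out
}

# 3x3 operator acting on amplitudes of a cos(kx) perturbation
mode_operator <- function(base, params, k, n_mode = 32, J = 5) {
  L <- if (k > 0) 2 * pi / k else 10
  grid <- veg_grid(L, n_mode, ny = 1)
  approx <- build_kernel_approx(params, grid, J = J)
  mode <- if (k > 0) cos(k * grid$x) else rep(1, n_mode)
  proj <- function(f) {
    if (k > 0) 2 * mean(as.vector(f) * mode) else mean(f)
  }
  mk_state <- function(vals) {
    structure(list(B1 = matrix(vals[[1]], n_mode, 1),
                   B2 = matrix(vals[[2]], n_mode, 1),
                   W = matrix(vals[[3]], n_mode, 1), T = 0),
              class = "veg_state")
  }
  M <- matrix(0, 3, 3)
  for (a in 1:3) {
    eps <- 1e-6 * max(1, abs(base[a]))
    up <- as.list(base); dn <- as.list(base)
    up[[a]] <- base[a] + eps * mode
    dn[[a]] <- base[a] - eps * mode
    rp <- veg_rhs(mk_state(up), params, grid, approx)
    rm <- veg_rhs(mk_state(dn), params, grid, approx)
    M[, a] <- c(proj(rp$dB1 - rm$dB1),
                proj(rp$dB2 - rm$dB2),
                proj(rp$dW - rm$dW)) / (2 * eps)
  }
  M
}

#' @export
print.dispersion_curve <- function(x, ...) {
  i <- which.max(x$lambda)
  cat(sprintf("<dispersion_curve> %d wavenumbers; max lambda = %.4g at k = %.4g\n",
              length(x$k), x$lambda[i], x$k[i]))
  invisible(x)
}

#' Locate a Turing (nonuniform stationary) instability threshold
#'
#' Bisects the precipitation rate for the sign change of the maximal
#' finite-wavenumber growth rate `max_k lambda(k)` on a uniform branch: below
#' the critical `P_c` a periodic mode of critical wavenumber `k_c > 0` grows.
#' The three defining conditions (`lambda = 0`, `d lambda/dk = 0`,
#' `d^2 lambda/dk^2 < 0`) are verified numerically at the returned point.
#'
#' @param params a [veg_params] (its `P` is ignored).
#' @param branch uniform branch label, e.g. `"GU"`.
#' @param P_lo,P_hi bisection bracket, mm/y.
#' @param tol bracket width at which to stop, mm/y.
#' @param k_grid wavenumbers scanned for the growing mode (`k > 0` only).
#' @return A `turing_point`: list with `P_c`, `k_c`, `branch`, `lambda_max`,
#'   and logical `conditions` (the three Turing conditions), or `NULL` if no
#'   sign change exists in the bracket (no Turing point).
#' @export
turing_threshold <- function(params, branch = "GU", P_lo, P_hi, tol = 1,
                             k_grid = default_k_grid(params)) {
  k_grid <- k_grid[k_grid > 0]
  maxlam <- function(P) {
    pp <- params; pp$P <- P
    eqs <- Filter(function(e) e$label == branch, uniform_equilibria(pp))
    if (length(eqs) == 0) return(NA_real_)
    # on multi-valued branches take the upper (large-biomass) solution
    eq <- eqs[[which.max(vapply(eqs, function(e) e$B1 + e$B2, numeric(1)))]]
    dc <- dispersion_relation(eq, pp, k_grid)
    max(dc$lambda)
  }
  f_lo <- maxlam(P_lo); f_hi <- maxlam(P_hi)
  if (is.na(f_lo) || is.na(f_hi) || sign(f_lo) == sign(f_hi)) return(NULL)
  lo <- P_lo; hi <- P_hi
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- maxlam(mid)
    if (is.na(fm)) return(NULL)
    if (sign(fm) == sign(f_lo)) { lo <- mid; f_lo <- fm } else hi <- mid
  }
  P_c <- (lo + hi) / 2
  pp <- params; pp$P <- P_c
  eqs <- Filter(function(e) e$label == branch, uniform_equilibria(pp))
  eq <- eqs[[which.max(vapply(eqs, function(e) e$B1 + e$B2, numeric(1)))]]
  dc <- dispersion_relation(eq, pp, k_grid)
  i <- which.max(dc$lambda)
  k_c <- dc$k[i]
  # refine locally and test the three conditions
  dk <- if (i > 1 && i < length(dc$k)) (dc$k[i + 1] - dc$k[i - 1]) / 2
        else diff(dc$k[1:2])
  kfine <- seq(max(k_c - dk, dc$k[1]), k_c + dk, length.out = 21)
  dcf <- dispersion_relation(eq, pp, kfine)
  j <- which.max(dcf$lambda)
  k_c <- dcf$k[j]
  h <- kfine[2] - kfine[1]
  d1 <- if (j > 1 && j < 21) (dcf$lambda[j + 1] - dcf$lambda[j - 1]) / (2 * h) else NA
  d2 <- if (j > 1 && j < 21)
    (dcf$lambda[j + 1] - 2 * dcf$lambda[j] + dcf$lambda[j - 1]) / h^2 else NA
  out <- list(P_c = P_c, k_c = k_c, branch = branch,
              lambda_max = dcf$lambda[j],
              conditions = c(lambda_zero = abs(dcf$lambda[j]) < 0.05,
                             interior_max = is.finite(d1) && abs(d1 * h) < 0.05,
                             curvature_neg = is.finite(d2) && d2 < 0))
  class(out) <- "turing_point"
  out
}

#' @export
print.turing_point <- function(x, ...) {
  cat(sprintf("<turing_point> branch %s: P_c = %.4g mm/y, k_c = %.4g 1/m\n",
              x$branch, x$P_c, x$k_c))
  invisible(x)
}
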