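# Uniform reduction of the model: kernel masses are (1 + E_i*B_i)^2 for the
# root kernels and 1 for the sucker kernels, so on uniform fields the
# dynamics collapse to three scalar ODEs.
uniform_rhs <- function(x, params) {
  B1 <- x[1]; B2 <- x[2]; W <- x[3]
  p <- params
  g1 <- p$Lam1 * W * (1 + p$E1 * B1)^2
  g2 <- p$Lam2 * W * (1 + p$E2 * B2)^2
  u1 <- p$Gam1 * B1 * (1 + p$E1 * B1)^2
  u2 <- p$Gam2 * B2 * (1 + p$E2 * B2)^2
  d1 <- p$Th1 * W / (W + p$Wstar1) * B1
  d2 <- p$Th2 * W / (W + p$Wstar2) * B2
  L <- p$N * (1 - p$R1 * B1 / p$K1 - p$R2 * B2 / p$K2)
  c(g1 * B1 * (1 - B1 / p$K1) - p$M1 * B1 + d1,
    g2 * B2 * (1 - B2 / p$K2) - p$M2 * B2 + d2,
    p$P - L * W - W * (u1 + u2))
}

# central finite-difference Jacobian
fd_jacobian <- function(f, x, eps = NULL) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    h <- if (is.null(eps)) 1e-7 * max(1, abs(x[i])) else eps
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# damped Newton with finite-difference Jacobian
newton_solve <- function(f, x0, tol = 1e-12, maxit = 60) {
  x <- x0
  for (it in seq_len(maxit)) {
    fx <- f(x)
    if (!all(is.finite(fx))) return(NULL)
    if (max(abs(fx)) < tol) return(list(x = x, res = max(abs(fx))))
    J <- fd_jacobian(f, x)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x - lam * step
      fn <- f(xn)
      if (all(is.finite(fn)) && sum(fn^2) < sum(fx^2)) break
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    x <- xn
  }
  fx <- f(x)
  if (max(abs(fx)) < tol) list(x = x, res = max(abs(fx))) else NULL
}

#' Uniform stationary states
#'
#' Finds the model's spatially uniform equilibria: bare soil (BS, analytic),
#' the shrub-only state (GU) and sedge-only state (CU) by 2-variable root
#' finding from a lattice of starting points, and the mixed state (MU) by
#' 3-variable root finding. Each state is tagged with its linear stability
#' to uniform perturbations (3x3 Jacobian).
#'
#' @param params a [veg_params].
#' @param nonuniform also assess stability to nonuniform (finite-k)
#'   perturbations via [dispersion_relation] (slower).
#' @param k_grid wavenumber grid for the nonuniform assessment.
#' @return A list of `uniform_equilibrium` objects, each with fields
#'   `B1, B2, W` (kg/m^2), `label` (BS/GU/CU/MU), `residual`,
#'   `stable_uniform`, `eig` (uniform-Jacobian eigenvalues), and
#'   `stable_nonuniform` (NA unless requested).
#' @export
uniform_equilibria <- function(params, nonuniform = FALSE,
                               k_grid = default_k_grid(params)) {
  p <- params
  eqs <- list()
  add <- function(eqs, B1, B2, W, label) {
    res <- max(abs(uniform_rhs(c(B1, B2, W), p)))
    for (e in eqs)
      if (abs(e$B1 - B1) < 1e-8 && abs(e$B2 - B2) < 1e-8 &&
          abs(e$W - W) < 1e-8) return(eqs)
    eq <- list(B1 = B1, B2 = B2, W = W, label = label, residual = res,
               stable_uniform = NA, eig = NULL, stable_nonuniform = NA)
    class(eq) <- "uniform_equilibrium"
    eqs[[length(eqs) + 1L]] <- eq
    eqs
  }

  eqs <- add(eqs, 0, 0, p$P / p$N, "BS")

  # single-species branches: solve the divided growth equation + water balance
  starts2 <- expand.grid(B = c(0.15, 0.4, 0.7, 0.95),
                         Wfrac = c(0.05, 0.5))
  for (sp in c(1, 2)) {
    K <- if (sp == 1) p$K1 else p$K2
    lab <- if (sp == 1) "GU" else "CU"
    f <- function(x) {
      full <- if (sp == 1) c(x[1], 0, x[2]) else c(0, x[1], x[2])
      r <- uniform_rhs(full, p)
      c(r[sp] / max(x[1], 1e-30), r[3])
    }
    for (s in seq_len(nrow(starts2))) {
      x0 <- c(starts2$B[s] * K, starts2$Wfrac[s] * p$P / p$N)
      sol <- newton_solve(f, x0, tol = 1e-11)
      if (!is.null(sol) && sol$x[1] > 1e-6 && sol$x[2] > 0) {
        eqs <- if (sp == 1) add(eqs, sol$x[1], 0, sol$x[2], lab)
               else add(eqs, 0, sol$x[1], sol$x[2], lab)
      }
    }
  }

  # mixed state: full 3-variable system with both growth equations divided
  f3 <- function(x) {
    r <- uniform_rhs(x, p)
    c(r[1] / max(x[1], 1e-30), r[2] / max(x[2], 1e-30), r[3])
  }
  starts3 <- expand.grid(B1 = c(0.2, 0.6) * p$K1, B2 = c(0.2, 0.6) * p$K2,
                         Wfrac = c(0.05, 0.5))
  for (s in seq_len(nrow(starts3))) {
    x0 <- c(starts3$B1[s], starts3$B2[s], starts3$Wfrac[s] * p$P / p$N)
    sol <- newton_solve(f3, x0, tol = 1e-11)
    if (!is.null(sol) && all(sol$x > c(1e-6, 1e-6, 0)))
      eqs <- add(eqs, sol$x[1], sol$x[2], sol$x[3], "MU")
  }

  eqs <- lapply(eqs, function(eq) {
    J <- uniform_jacobian(eq, p)
    ev <- eigen(J, only.values = TRUE)$values
    eq$eig <- ev
    eq$stable_uniform <- max(Re(ev)) < 1e-8
    eq
  })
  if (nonuniform) {
    eqs <- lapply(eqs, function(eq) {
      dc <- dispersion_relation(eq, p, k_grid)
      eq$stable_nonuniform <- max(dc$lambda) < 1e-8
      eq
    })
  }
  eqs
}

#' Uniform 3x3 Jacobian
#'
#' Jacobian of the uniform (zero-wavenumber) reduction at an equilibrium,
#' by central finite differences of the scalar system.
#'
#' @param eq a `uniform_equilibrium` (or list with `B1, B2, W`).
#' @param params a [veg_params].
#' @return 3x3 matrix.
#' @export
uniform_jacobian <- function(eq, params) {
  fd_jacobian(function(x) uniform_rhs(x, params), c(eq$B1, eq$B2, eq$W))
}

#' @export
print.uniform_equilibrium <- function(x, ...) {
  cat(sprintf("<%s> B1 = %.6g, B2 = %.6g, W = %.6g (residual %.2g, %s)\n",
              x$label, x$B1, x$B2, x$W, x$residual,
              if (isTRUE(x$stable_uniform)) "stable" else "unstable"))
  invisible(x)
}

# growth eigenvalue of species i invading bare soil at water level W = P/N:
# linearization of the biomass equation at B = 0
bare_soil_growth_rate <- function(params, species = 1) {
  W <- params$P / params$N
  if (species == 1)
    params$Lam1 * W - params$M1 + params$Th1 * W / (W + params$Wstar1)
  else
    params$Lam2 * W - params$M2 + params$Th2 * W / (W + params$Wstar2)
}
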