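#' Fixed-width approximation of the biomass-dependent root kernel
#'
#' The nonlocal growth term is not a convolution because the Gaussian root
#' kernel's width depends on the local biomass. Following the standard
#' linear-combination-of-convolutions device, the biomass-dependent kernel is
#' approximated by `J` fixed-width Gaussians with biomass-dependent weights:
#' widths are placed at `J` nodes of `S(B) = SG1 * (1 + E1 * B)` uniform in
#' `B` over `[0, K1]`, weights interpolate piecewise-linearly between the two
#' bracketing widths and are rescaled so the total kernel mass equals
#' `(1 + E1 * B)^2` exactly for every `B` (node-exact by construction).
#'
#' The returned object also carries the grid transfer functions of the two
#' fat-tailed sucker/dispersal kernels and of the spectral Laplacian, i.e.
#' everything the right-hand side needs beyond the state itself.
#'
#' @param params a [veg_params].
#' @param grid a [veg_grid].
#' @param J number of fixed widths (default 5, the reference choice).
#' @return An object of class `kernel_approx`.
#' @export
build_kernel_approx <- function(params, grid, J = 5) {
  stopifnot(J >= 2)
  Bnodes <- seq(0, params$K1, length.out = J)
  S <- params$SG1 * (1 + params$E1 * Bnodes)
  mass <- (1 + params$E1 * Bnodes)^2
  Kroot <- array(0, dim = c(grid$nx, grid$ny, J))
  for (j in seq_len(J))
    Kroot[, , j] <- kernel_hat_gaussian(grid$kmag, S[j], mass[j])
  Ks1 <- kernel_hat_sucker(grid$kmag, params$SD1)
  Ks2 <- if (params$cyperus_local) matrix(1, grid$nx, grid$ny)
         else kernel_hat_sucker(grid$kmag, params$SD2)
  a <- list(J = as.integer(J), Bnodes = Bnodes, widths = S, mass = mass,
            dB_node = Bnodes[2] - Bnodes[1],
            Kroot = Kroot, Ks1 = Ks1, Ks2 = matrix(Ks2, grid$nx, grid$ny),
            lap = -grid$k2, grid = grid,
            E1 = params$E1, K1 = params$K1)
  class(a) <- "kernel_approx"
  a
}

#' Interpolation weights of the kernel approximation
#'
#' For each biomass value, the weight vector `w(B)` of length `J` such that
#' `sum_j w_j(B) * mass_j = (1 + E1 * B)^2` exactly, with at most two nonzero
#' entries (the bracketing width nodes). Values above the last node are
#' carried by the last node alone (pure mass rescale); this only occurs for
#' transient overshoots beyond `K1`.
#'
#' @param B numeric vector/matrix of biomass values.
#' @param approx a [build_kernel_approx] result.
#' @return A matrix `length(B) x J` of nonnegative weights.
#' @export
kernel_weights <- function(B, approx) {
  Bv <- as.vector(B)
  J <- approx$J
  u <- Bv / approx$dB_node
  j0 <- pmin(pmax(floor(u), 0), J - 2)       # 0-based lower node
  # t is left unclamped below 0 / above 1 at the extreme segments: linear
  # extrapolation keeps the map B -> w(B) kink-free at B = 0 (important for
  # finite-difference linearization); fields are nonnegative in simulation
  t <- u - j0
  mlo <- approx$mass[j0 + 1]
  mhi <- approx$mass[j0 + 2]
  denom <- (1 - t) * mlo + t * mhi
  resc <- ifelse(denom > 0.1, (1 + approx$E1 * Bv)^2 / denom, 0)
  w <- matrix(0, length(Bv), J)
  idx <- seq_along(Bv)
  w[cbind(idx, j0 + 1)] <- resc * (1 - t)
  w[cbind(idx, j0 + 2)] <- w[cbind(idx, j0 + 2)] + resc * t
  w
}

#' @export
print.kernel_approx <- function(x, ...) {
  cat(sprintf("<kernel_approx> J = %d widths %s m on %d x %d grid\n",
              x$J, paste(signif(x$widths, 3), collapse = ", "),
              x$grid$nx, x$grid$ny))
  invisible(x)
}

#' Dump the kernel-approximation table
#'
#' Writes the width nodes, node masses and a sampled weight table to a
#' delimited text file for inspection.
#'
#' @param approx a `kernel_approx`.
#' @param file output path.
#' @param nB number of biomass samples.
#' @export
dump_kernel_table <- function(approx, file, nB = 50) {
  B <- seq(0, approx$K1, length.out = nB)
  w <- kernel_weights(B, approx)
  colnames(w) <- paste0("w", seq_len(approx$J))
  df <- data.frame(B = B, mass = (1 + approx$E1 * B)^2, w)
  write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
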