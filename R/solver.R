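# list handed to the compiled core (plain numerics only)
core_precomp <- function(params, approx) {
  list(params = unclass(params), J = approx$J, mass = approx$mass,
       dB_node = approx$dB_node, Kroot = approx$Kroot,
       Ks1 = approx$Ks1, Ks2 = approx$Ks2, lap = approx$lap)
}

#' Solver configuration
#'
#' @param dt time step, y. The default resolves the stiffest sink rates of
#'   the reference parameters (water uptake under a full-grown shrub canopy
#'   approaches 1e3 1/y, and explicit RK4 requires `dt < 2.8/rate`).
#' @param t_max integration horizon, y.
#' @param steady_tol steady-state threshold: mean absolute per-step change,
#'   summed over the three fields, kg/m^2 per step.
#' @param snapshot_every interval between stored snapshots/diagnostics, y.
#' @param store_fields keep full field snapshots (set `FALSE` for long runs
#'   where only diagnostics and the final state are needed).
#' @param clip clip negative field values to zero after each step (RK4 can
#'   undershoot); the clipped mass is accumulated and reported.
#' @param census_threshold biomass threshold for the per-snapshot shrub spot
#'   census, kg/m^2 (`NULL` disables the census).
#' @param seed integer seed recorded in the run manifest (any stochastic
#'   initial condition should be generated with it).
#' @param engine `"cpp"` (compiled core) or `"r"` (reference implementation).
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(dt = 1e-3, t_max = 100, steady_tol = 1e-9,
                           snapshot_every = 1, store_fields = TRUE,
                           clip = TRUE, census_threshold = NULL,
                           seed = NULL, engine = c("cpp", "r")) {
  stopifnot(dt > 0, t_max > 0, steady_tol > 0, snapshot_every > 0)
  ctl <- list(dt = dt, t_max = t_max, steady_tol = steady_tol,
              snapshot_every = snapshot_every, store_fields = store_fields,
              clip = clip, census_threshold = census_threshold,
              seed = seed, engine = match.arg(engine))
  class(ctl) <- "solver_control"
  ctl
}

#' One RK4 step
#'
#' Advances the state by a single classical fourth-order Runge-Kutta step of
#' the model right-hand side; the diffusion term uses the exact spectral
#' Laplacian. Negative undershoots are clipped to zero when `clip = TRUE`.
#'
#' @param state a [veg_state].
#' @param params,grid,approx model setup (see [veg_rhs]).
#' @param dt time step, y.
#' @param clip clip negatives after the step.
#' @param engine `"cpp"` or `"r"`.
#' @return The advanced [veg_state]; attributes `clipped` (mass removed by
#'   clipping, field units summed over cells) and `minval` (most negative
#'   pre-clip value seen).
#' @export
rk4_step <- function(state, params, grid, approx, dt, clip = TRUE,
                     engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    res <- core_step(state$B1, state$B2, state$W,
                     core_precomp(params, approx), dt, clip)
    out <- state
    out$B1 <- res$B1; out$B2 <- res$B2; out$W <- res$W
    out$T <- state$T + dt
    attr(out, "clipped") <- res$clipped
    attr(out, "minval") <- res$minval
    return(out)
  }
  add <- function(s, k, h) {
    r <- s
    r$B1 <- s$B1 + h * k$dB1; r$B2 <- s$B2 + h * k$dB2; r$W <- s$W + h * k$dW
    r
  }
  k1 <- veg_rhs(state, params, grid, approx)
  k2 <- veg_rhs(add(state, k1, dt / 2), params, grid, approx)
  k3 <- veg_rhs(add(state, k2, dt / 2), params, grid, approx)
  k4 <- veg_rhs(add(state, k3, dt), params, grid, approx)
  out <- state
  for (nm in c("B1", "B2", "W")) {
    dnm <- paste0("d", nm)
    out[[nm]] <- state[[nm]] +
      dt / 6 * (k1[[dnm]] + 2 * k2[[dnm]] + 2 * k3[[dnm]] + k4[[dnm]])
  }
  minval <- min(out$B1, out$B2, out$W)
  clipped <- 0
  if (clip && minval < 0) {
    for (nm in c("B1", "B2", "W")) {
      neg <- out[[nm]] < 0
      clipped <- clipped - sum(out[[nm]][neg])
      out[[nm]][neg] <- 0
    }
  }
  out$T <- state$T + dt
  attr(out, "clipped") <- clipped
  attr(out, "minval") <- minval
  out
}

#' Integrate to a steady state or horizon
#'
#' Advances the model until `t_max`, until the mean absolute per-step change
#' drops below `steady_tol` (asymptotic steady state), or until a
#' user-supplied early-stopping rule fires. Snapshots and diagnostics
#' (spatial means, optional shrub spot count) are recorded every
#' `snapshot_every` years.
#'
#' @param state initial [veg_state].
#' @param params,grid,approx model setup (see [veg_rhs]).
#' @param control a [solver_control].
#' @param stop_fn optional `function(state, diagnostics_df)` returning `TRUE`
#'   to terminate early (checked once per snapshot interval).
#' @return A `veg_trajectory`: list with `times`, `snapshots` (list of
#'   [veg_state] or `NULL`), `diagnostics` (data frame with columns `t`,
#'   `meanB1`, `meanB2`, `meanW`, and `spots` when the census is enabled),
#'   `final` state, `termination` (`"steady"`, `"horizon"`, `"stopped"` or
#'   `"blowup"`), and `clipped_mass`.
#' @export
integrate_model <- function(state, params, grid, approx,
                            control = solver_control(), stop_fn = NULL) {
  ctl <- control
  pre <- if (ctl$engine == "cpp") core_precomp(params, approx) else NULL
  chunk_steps <- max(1L, round(ctl$snapshot_every / ctl$dt))
  n_chunks <- ceiling(ctl$t_max / ctl$snapshot_every)

  diag_row <- function(s) {
    m <- state_means(s)
    row <- data.frame(t = s$T, meanB1 = m[["B1"]], meanB2 = m[["B2"]],
                      meanW = m[["W"]])
    if (!is.null(ctl$census_threshold))
      row$spots <- detect_spots(s$B1, ctl$census_threshold, grid)$count
    row
  }

  times <- state$T
  snapshots <- if (ctl$store_fields) list(state) else list(NULL)
  diagnostics <- diag_row(state)
  clipped <- 0
  minval <- 0
  termination <- "horizon"
  cur <- state

  for (ch in seq_len(n_chunks)) {
    if (ctl$engine == "cpp") {
      res <- core_integrate(cur$B1, cur$B2, cur$W, pre, ctl$dt,
                            chunk_steps, ctl$steady_tol, ctl$clip)
      cur$B1 <- res$B1; cur$B2 <- res$B2; cur$W <- res$W
      cur$T <- cur$T + res$steps * ctl$dt
      clipped <- clipped + res$clipped
      minval <- min(minval, res$minval)
      steady <- res$steady
      if (res$blowup) { termination <- "blowup"; break }
    } else {
      steady <- FALSE
      for (s in seq_len(chunk_steps)) {
        prev <- cur
        cur <- rk4_step(cur, params, grid, approx, ctl$dt, ctl$clip, "r")
        clipped <- clipped + attr(cur, "clipped")
        minval <- min(minval, attr(cur, "minval"))
        change <- mean(abs(cur$B1 - prev$B1)) + mean(abs(cur$B2 - prev$B2)) +
          mean(abs(cur$W - prev$W))
        if (change < ctl$steady_tol) { steady <- TRUE; break }
      }
    }
    times <- c(times, cur$T)
    snapshots[[length(snapshots) + 1L]] <- if (ctl$store_fields) cur else NULL
    diagnostics <- rbind(diagnostics, diag_row(cur))
    if (steady) { termination <- "steady"; break }
    if (!is.null(stop_fn) && isTRUE(stop_fn(cur, diagnostics))) {
      termination <- "stopped"
      break
    }
  }
  if (termination == "blowup")
    warning("integration aborted: non-finite values (last valid state kept)")

  traj <- list(times = times, snapshots = snapshots,
               diagnostics = diagnostics, final = cur,
               termination = termination, clipped_mass = clipped,
               min_field_value = minval,
               control = ctl, params = params, grid = grid)
  class(traj) <- "veg_trajectory"
  traj
}

#' @export
print.veg_trajectory <- function(x, ...) {
  cat(sprintf("<veg_trajectory> %d snapshots to T = %g y (%s)\n",
              length(x$times), x$final$T, x$termination))
  invisible(x)
}
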