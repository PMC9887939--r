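#' Detect shrub spots (connected components on the periodic grid)
#'
#' Labels connected components of `{B1 > threshold}` under periodic
#' 4-connectivity (2-connectivity in 1D) and reports a census: count,
#' centroids (periodic-mean convention), areas, and peak biomass.
#'
#' @param B1 shrub biomass field (matrix, or vector in 1D).
#' @param threshold detection threshold, kg/m^2 (default `0.1 * K1` is the
#'   conventional choice; must be `> 0`).
#' @param grid the [veg_grid].
#' @return A `spot_census`: list with `count`, `threshold` and data frame
#'   `spots` (columns `x`, `y`, `area_m2`, `peakB1`).
#' @export
detect_spots <- function(B1, threshold, grid) {
  stopifnot(threshold > 0)
  if (is.null(dim(B1))) B1 <- matrix(B1, ncol = 1)
  mask <- B1 > threshold
  idx <- which(mask)
  spots <- data.frame(x = numeric(0), y = numeric(0),
                      area_m2 = numeric(0), peakB1 = numeric(0))
  if (length(idx) > 0) {
    comp <- label_components(mask, grid)
    labs <- comp[idx]
    for (l in sort(unique(labs))) {
      cells <- idx[labs == l]
      ij <- arrayInd(cells, dim(B1))
      spots <- rbind(spots, data.frame(
        x = periodic_mean(grid$x[ij[, 1]], grid$Lx),
        y = if (is_1d(grid)) 0 else periodic_mean(grid$y[ij[, 2]], grid$Ly),
        area_m2 = length(cells) * grid$dA,
        peakB1 = max(B1[cells])))
    }
  }
  out <- list(count = nrow(spots), threshold = threshold, spots = spots)
  class(out) <- "spot_census"
  out
}

#' @export
print.spot_census <- function(x, ...) {
  cat(sprintf("<spot_census> %d spot(s) above %.3g kg/m^2\n",
              x$count, x$threshold))
  invisible(x)
}

# connected-component labels of a logical mask with periodic wraparound,
# via igraph components over the 4-neighbour adjacency of masked cells
label_components <- function(mask, grid) {
  nx <- nrow(mask); ny <- ncol(mask)
  idx <- which(mask)
  lab <- rep(NA_integer_, nx * ny)
  if (length(idx) == 0) return(matrix(lab, nx, ny))
  pos <- match(seq_len(nx * ny), idx)  # cell -> vertex id (NA outside mask)
  ij <- arrayInd(idx, c(nx, ny))
  right <- (ij[, 1] %% nx) + 1 + (ij[, 2] - 1) * nx
  edges <- cbind(seq_along(idx), pos[right])
  if (ny > 1) {
    up <- ij[, 1] + (ij[, 2] %% ny) * nx
    edges <- rbind(edges, cbind(seq_along(idx), pos[up]))
  }
  edges <- edges[!is.na(edges[, 2]), , drop = FALSE]
  g <- igraph::make_graph(edges = as.vector(t(edges)), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp[seq_along(idx)]
  matrix(lab, nx, ny)
}

# mean of positions on a circle of circumference L
periodic_mean <- function(x, L) {
  th <- 2 * pi * x / L
  m <- atan2(mean(sin(th)), mean(cos(th)))
  (m %% (2 * pi)) * L / (2 * pi)
}

#' Radial profiles and bare-soil halo of an isolated spot
#'
#' Angle-averaged radial profiles of `B1`, `B2` and `W` about a spot centre,
#' with the halo annulus (radii where both biomasses are below threshold
#' between the shrub core and the surrounding sedge field) and the radius of
#' the soil-water minimum — the model analogue of the lowest water potential
#' sitting in the bare halo.
#'
#' @param state a [veg_state] containing an isolated spot.
#' @param center numeric `c(x, y)` (m); `c(x)` in 1D.
#' @param grid the [veg_grid].
#' @param threshold biomass threshold for core/halo delimitation, kg/m^2.
#' @return A `halo_profile`: list with data frame `profile` (`r, B1, B2, W`),
#'   `core_radius`, `halo` (`c(r_in, r_out)` or `NULL` if no halo),
#'   `w_min_radius`, and `w_min_in_halo` (is the water minimum inside or at
#'   the inner edge of the halo annulus?).
#' @export
halo_profile <- function(state, center, grid, threshold = 0.1 * max(state$B1)) {
  if (max(state$B1) <= threshold)
    stop("no spot above threshold at the requested centre")
  wrapd <- function(d, L) {
    d <- abs(d) %% L
    pmin(d, L - d)
  }
  dx <- wrapd(grid$x - center[1], grid$Lx)
  dyv <- if (is_1d(grid)) 0 else
    wrapd(grid$y - (if (length(center) > 1) center[2] else 0), grid$Ly)
  r <- sqrt(outer(dx^2, rep(1, grid$ny)) + outer(rep(1, grid$nx), dyv^2))
  rb <- floor(r / grid$dx + 0.5)
  agg <- function(f) as.vector(tapply(as.vector(f), as.vector(rb), mean))
  radii <- sort(unique(as.vector(rb))) * grid$dx
  prof <- data.frame(r = radii, B1 = agg(state$B1), B2 = agg(state$B2),
                     W = agg(state$W))
  if (prof$B1[1] <= threshold) stop("no spot centred at the requested point")
  core_end <- which(prof$B1 <= threshold)[1]          # first radius off-core
  core_radius <- prof$r[max(core_end - 1, 1)]
  bare <- prof$B1 <= threshold & prof$B2 <= threshold
  halo <- NULL
  i <- core_end
  if (!is.na(i) && i <= nrow(prof) && bare[i]) {
    j <- i
    while (j < nrow(prof) && bare[j + 1]) j <- j + 1
    halo <- c(prof$r[i], prof$r[j])
  }
  w_min_radius <- prof$r[which.min(prof$W)]
  w_min_in_halo <- !is.null(halo) &&
    w_min_radius >= core_radius && w_min_radius <= halo[2]
  out <- list(profile = prof, core_radius = core_radius, halo = halo,
              w_min_radius = w_min_radius, w_min_in_halo = w_min_in_halo,
              threshold = threshold)
  class(out) <- "halo_profile"
  out
}

#' @export
print.halo_profile <- function(x, ...) {
  cat(sprintf("<halo_profile> core r = %.3g m; halo %s; W min at r = %.3g m\n",
              x$core_radius,
              if (is.null(x$halo)) "absent"
              else sprintf("[%.3g, %.3g] m", x$halo[1], x$halo[2]),
              x$w_min_radius))
  invisible(x)
}
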