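#' Uniform state plus small noise
#'
#' Standard seeding for pattern-formation runs: independent uniform noise in
#' `[-amplitude, amplitude]` added to the biomass fields only (soil water
#' relaxes fast and the instability is biomass-driven), clipped at zero.
#'
#' @param equilibrium a `uniform_equilibrium` (or list with `B1, B2, W`).
#' @param amplitude noise amplitude, kg/m^2 (`>= 0`, much smaller than the
#'   biomass scales).
#' @param seed integer seed; the field is reproducible given the seed.
#' @param grid a [veg_grid].
#' @return A [veg_state].
#' @export
ic_uniform_plus_noise <- function(equilibrium, amplitude, seed, grid) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  n <- grid$nx * grid$ny
  set.seed(seed)
  noise <- function() matrix(runif(n, -amplitude, amplitude), grid$nx, grid$ny)
  veg_state(pmax(equilibrium$B1 + noise(), 0),
            pmax(equilibrium$B2 + noise(), 0),
            matrix(equilibrium$W, grid$nx, grid$ny), grid = grid)
}

#' Invader spots on a uniform background
#'
#' Shrub biomass as a sum of Gaussian bumps added to a uniform background
#' equilibrium (sedge and water fields stay at the background values).
#' Out-of-domain centres wrap periodically; overlapping bumps add.
#'
#' @param background a `uniform_equilibrium` (typically the sedge-only state).
#' @param centers matrix of centre coordinates (rows `c(x, y)`; `c(x, 0)` in
#'   1D), m. Zero rows return the unchanged background.
#' @param radius bump footprint radius (Gaussian sigma), m (`>= 2 * dx`).
#' @param peak bump peak biomass, kg/m^2.
#' @param grid a [veg_grid].
#' @return A [veg_state].
#' @export
ic_spots <- function(background, centers, radius, peak, grid) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = length(centers))
  if (nrow(centers) > 0 && radius < 2 * grid$dx)
    stop("spot radius must be at least 2 * dx")
  B1 <- matrix(background$B1, grid$nx, grid$ny)
  wrapd <- function(d, L) {
    d <- abs(d) %% L
    pmin(d, L - d)
  }
  for (s in seq_len(nrow(centers))) {
    dx <- wrapd(grid$x - centers[s, 1] %% grid$Lx, grid$Lx)
    dy <- if (is_1d(grid)) 0 else
      wrapd(grid$y - (if (ncol(centers) > 1) centers[s, 2] else 0) %% grid$Ly,
            grid$Ly)
    r2 <- outer(dx^2, rep(1, grid$ny)) + outer(rep(1, grid$nx), dy^2)
    B1 <- B1 + peak * exp(-r2 / (2 * radius^2))
  }
  veg_state(B1, matrix(background$B2, grid$nx, grid$ny),
            matrix(background$W, grid$nx, grid$ny), grid = grid)
}

#' Two uniform states joined across a smooth interface
#'
#' A tanh blend between two uniform equilibria of the same parameters across
#' a vertical interface at `x = Lx/2` (periodic, so a second interface sits
#' at the boundary). Used to study front motion between coexisting states.
#'
#' @param left_state,right_state uniform equilibria (lists with `B1, B2, W`).
#' @param interface_width tanh width, m; `0` gives a step profile.
#' @param grid a [veg_grid].
#' @return A [veg_state].
#' @export
ic_adjacent_patches <- function(left_state, right_state, interface_width, grid) {
  x <- grid$x
  half <- grid$Lx / 2
  blend <- if (interface_width > 0) {
    0.5 * (tanh((x - grid$Lx / 4) / interface_width) -
           tanh((x - 3 * grid$Lx / 4) / interface_width))
  } else {
    as.numeric(x >= grid$Lx / 4 & x < 3 * grid$Lx / 4)
  }
  mix <- function(a, b) {
    prof <- a * (1 - blend) + b * blend
    matrix(prof, grid$nx, grid$ny)
  }
  veg_state(mix(left_state$B1, right_state$B1),
            mix(left_state$B2, right_state$B2),
            mix(left_state$W, right_state$W), grid = grid)
}

# ---- scenario library ------------------------------------------------------

#' Bundled scenarios
#'
#' Named, fully reproducible experiment setups: a preset, a grid, an
#' initial-condition generator and a seed. `make_scenario()` resolves one
#' into concrete objects; the returned state is bit-identical when
#' regenerated from the manifest.
#'
#' Library: `single_spot` (stationary-spot experiment), `noisy_pattern`
#' (noise-seeded patterning), `adjacent_patches` (front motion at high
#' altitude), `four_spot_dry` / `four_spot_wet` (incomplete vs complete
#' invasion), `weak_feedback_control` (non-patterning invasion control),
#' `invasion_threshold_1d` (1D single-spot threshold probe).
#'
#' @param name scenario id.
#' @param overrides named list of scenario-field overrides (e.g.
#'   `list(P = 1250, nx = 128)`).
#' @return A `veg_scenario` list with `name, params, grid, state, seed,
#'   manifest` fields.
#' @export
make_scenario <- function(name = c("single_spot", "noisy_pattern",
                                   "adjacent_patches", "four_spot_dry",
                                   "four_spot_wet", "weak_feedback_control",
                                   "invasion_threshold_1d"),
                          overrides = list()) {
  name <- match.arg(name)
  def <- scenario_defaults[[name]]
  def <- modifyList(def, overrides)
  params <- do.call(preset_params, c(list(name = def$preset), def$param_overrides))
  grid <- if (identical(def$dim, 1L)) veg_grid(def$L, def$nx, ny = 1)
          else veg_grid(def$L, def$nx)
  state <- build_scenario_state(def, params, grid)
  man <- def
  man$name <- name
  sc <- list(name = name, params = params, grid = grid, state = state,
             seed = def$seed, manifest = man)
  class(sc) <- "veg_scenario"
  sc
}

scenario_defaults <- list(
  # domains are chosen to hold the low-altitude pattern wavelength (~13 m):
  # a spot plus its halo needs >~2 wavelengths of clearance before the
  # periodic images interact, and the four-spot square (side 0.3 L) needs
  # spot separations of at least one wavelength
  single_spot = list(preset = "low_altitude", param_overrides = list(),
                     dim = 2L, L = 32, nx = 64, kind = "spots", n_spots = 1,
                     radius = 1, peak_frac = 0.5, seed = 1L),
  noisy_pattern = list(preset = "low_altitude", param_overrides = list(),
                       dim = 1L, L = 64, nx = 256, kind = "noise",
                       background = "GU", amplitude = 1e-3, seed = 1L),
  adjacent_patches = list(preset = "high_altitude", param_overrides = list(),
                          dim = 1L, L = 64, nx = 256, kind = "patches",
                          left = "GU", right = "CU", interface_width = 1,
                          seed = 1L),
  four_spot_dry = list(preset = "low_altitude", param_overrides = list(P = 1000),
                       dim = 2L, L = 48, nx = 96, kind = "spots", n_spots = 4,
                       radius = 1, peak_frac = 0.5, seed = 1L),
  four_spot_wet = list(preset = "low_altitude", param_overrides = list(P = 1400),
                       dim = 2L, L = 48, nx = 96, kind = "spots", n_spots = 4,
                       radius = 1, peak_frac = 0.5, seed = 1L),
  weak_feedback_control = list(preset = "weak_feedback",
                               param_overrides = list(), dim = 2L, L = 48,
                               nx = 96, kind = "spots", n_spots = 4,
                               radius = 1, peak_frac = 0.5, seed = 1L),
  invasion_threshold_1d = list(preset = "low_altitude",
                               param_overrides = list(), dim = 1L, L = 128,
                               nx = 512, kind = "spots", n_spots = 1,
                               radius = 1, peak_frac = 0.5, seed = 1L)
)

build_scenario_state <- function(def, params, grid) {
  eqs <- uniform_equilibria(params)
  get_eq <- function(lab) {
    cand <- Filter(function(e) e$label == lab, eqs)
    if (length(cand) == 0) stop("scenario needs a ", lab, " state, none found")
    cand[[which.max(vapply(cand, function(e) e$B1 + e$B2, numeric(1)))]]
  }
  switch(def$kind,
    spots = ic_spots(get_eq("CU"), spot_centers(grid, def$n_spots),
                     radius = def$radius, peak = def$peak_frac * params$K1,
                     grid = grid),
    noise = ic_uniform_plus_noise(get_eq(def$background), def$amplitude,
                                  def$seed, grid),
    patches = ic_adjacent_patches(get_eq(def$left), get_eq(def$right),
                                  def$interface_width, grid),
    stop("unknown scenario kind ", def$kind))
}

#' @export
print.veg_scenario <- function(x, ...) {
  cat(sprintf("<veg_scenario> %s: preset %s, %s, seed %d\n", x$name,
              x$manifest$preset,
              if (is_1d(x$grid)) sprintf("1D n = %d", x$grid$nx)
              else sprintf("2D %d x %d", x$grid$nx, x$grid$ny),
              x$seed))
  invisible(x)
}

#' Write / read a scenario manifest
#'
#' The manifest (JSON) contains everything needed to regenerate the
#' scenario's initial state bit-identically: preset, parameter overrides,
#' grid, generator id and arguments, and seed.
#'
#' @param scenario a `veg_scenario`.
#' @param file path.
#' @export
write_manifest <- function(scenario, file) {
  jsonlite::write_json(scenario$manifest, file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(file) {
  man <- jsonlite::read_json(file, simplifyVector = TRUE)
  name <- man$name
  man$name <- NULL
  if (is.data.frame(man$param_overrides)) man$param_overrides <-
    as.list(man$param_overrides)
  man$param_overrides <- as.list(man$param_overrides)
  man$dim <- as.integer(man$dim)
  man$seed <- as.integer(man$seed)
  make_scenario(name, overrides = man)
}
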