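# Shared fixtures. Heavy objects are built lazily and cached for the whole
# test run; everything is generated in code (no stored data).

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# smooth positive random field on a grid (low-pass filtered uniform noise)
smooth_field <- function(grid, amp, seed, floor = 0) {
  set.seed(seed)
  f <- matrix(runif(grid$nx * grid$ny), grid$nx, grid$ny)
  f <- Re(fft(fft(f) * exp(-2 * grid$k2), inverse = TRUE)) / length(f)
  floor + amp * (f - min(f)) / (max(f) - min(f))
}

low_params <- function(...) preset_params("low_altitude", ...)

small_grid_2d <- function() cached("g2d", veg_grid(12, 48))
small_grid_1d <- function() cached("g1d", veg_grid(64, 256, ny = 1))

low_eqs <- function() cached("eqs_low", uniform_equilibria(low_params()))
eq_get <- function(eqs, lab) {
  cand <- Filter(function(e) e$label == lab, eqs)
  stopifnot(length(cand) > 0)
  cand[[which.max(vapply(cand, function(e) e$B1 + e$B2, numeric(1)))]]
}

# converged single-spot state (2D, low altitude, P = 1000), shared between
# the halo acceptance test and unit tests; 64 x 64, a few minutes once
single_spot_run <- function() cached("spot_run", {
  sc <- make_scenario("single_spot")
  approx <- build_kernel_approx(sc$params, sc$grid)
  ctl <- solver_control(t_max = 50, dt = 2e-3, store_fields = TRUE,
                        snapshot_every = 2,
                        census_threshold = 0.1 * sc$params$K1)
  integrate_model(sc$state, sc$params, sc$grid, approx, ctl)
})
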