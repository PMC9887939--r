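test_that("compiled core and R reference agree on rhs and on one RK4 step", {
  p <- low_params()
  g <- small_grid_2d()
  a <- build_kernel_approx(p, g)
  st <- veg_state(smooth_field(g, 0.6, 31), smooth_field(g, 0.3, 32),
                  smooth_field(g, 10, 33, floor = 2), grid = g)
  r_r <- veg_rhs(st, p, g, a)
  r_c <- rootpattern:::core_rhs(st$B1, st$B2, st$W,
                                rootpattern:::core_precomp(p, a))
  expect_equal(r_r$dB1, r_c$dB1, tolerance = 1e-12)
  expect_equal(r_r$dB2, r_c$dB2, tolerance = 1e-12)
  expect_equal(r_r$dW, r_c$dW, tolerance = 1e-12)
  s_r <- rk4_step(st, p, g, a, 1e-3, engine = "r")
  s_c <- rk4_step(st, p, g, a, 1e-3, engine = "cpp")
  expect_equal(s_r$B1, s_c$B1, tolerance = 1e-12)
  expect_equal(s_r$W, s_c$W, tolerance = 1e-12)
})

test_that("bare-soil equilibrium is a fixed point of the stepper", {
  p <- low_params()
  g <- small_grid_2d()
  a <- build_kernel_approx(p, g)
  bs <- uniform_state(g, 0, 0, p$P / p$N)
  out <- rk4_step(bs, p, g, a, 0.01)
  expect_equal(out$B1, bs$B1)
  expect_equal(out$W, bs$W, tolerance = 1e-12)
})

test_that("pure-diffusion mode decays at the exact heat-equation rate to
           RK4 accuracy", {
  # biology switched off; a single Fourier mode of W must decay by
  # exp(-DW k^2 dt) per step with O(dt^5) one-step defect
  g <- veg_grid(10, 32, ny = 1)
  p <- suppressWarnings(veg_params(P = 1e-12, N = 1e-12, Lam1 = 1e-12,
    Lam2 = 1e-12, Gam1 = 1e-12, Gam2 = 1e-12, Th1 = 1e-12, Th2 = 1e-12,
    M1 = 1e-12, M2 = 1e-12, DW = 0.5))
  a <- build_kernel_approx(p, g)
  k <- g$kx[4]  # third harmonic
  W0 <- 10 + cos(k * g$x)
  st <- veg_state(matrix(0, g$nx, 1), matrix(0, g$nx, 1), matrix(W0), grid = g)
  for (dt in c(0.02, 0.01)) {
    out <- rk4_step(st, p, g, a, dt, clip = FALSE)
    amp <- 2 * mean((out$W - mean(out$W)) * cos(k * g$x))
    exact <- exp(-p$DW * k^2 * dt)
    defect <- abs(amp - exact)
    z <- p$DW * k^2 * dt
    # RK4 one-step truncation of exp(-z): z^5/120 leading term
    expect_lt(defect, 2 * z^5 / 120)
  }
})

test_that("step self-convergence is fourth order (Richardson)", {
  p <- low_params()
  g <- veg_grid(16, 32, ny = 1)
  # J = 2 keeps biomass inside a single interpolation segment, so the rhs is
  # smooth and the clean RK4 order is visible (interior weight nodes add
  # C0 kinks by design)
  a <- build_kernel_approx(p, g, J = 2)
  st <- veg_state(matrix(smooth_field(g, 0.4, 41)), matrix(smooth_field(g, 0.2, 42)),
                  matrix(smooth_field(g, 8, 43, floor = 2)), grid = g)
  advance <- function(dt, nsteps) {
    s <- st
    for (i in seq_len(nsteps)) s <- rk4_step(s, p, g, a, dt, clip = FALSE)
    s
  }
  Tfin <- 0.04
  s1 <- advance(2e-3, Tfin / 2e-3)
  s2 <- advance(1e-3, Tfin / 1e-3)
  s3 <- advance(5e-4, Tfin / 5e-4)
  e1 <- max(abs(s1$W - s3$W), abs(s1$B1 - s3$B1))
  e2 <- max(abs(s2$W - s3$W), abs(s2$B1 - s3$B1))
  expect_gt(e1 / e2, 10)  # ~16 for clean 4th order (Richardson ratio)
})

test_that("integrate_model: steady detection, fixed-point preservation and
           determinism", {
  p <- low_params()
  g <- small_grid_1d()
  a <- build_kernel_approx(p, g)
  cu <- eq_get(low_eqs(), "CU")
  st <- uniform_state(g, cu$B1, cu$B2, cu$W)
  ctl <- solver_control(t_max = 5, dt = 1e-3, snapshot_every = 0.5)
  traj <- integrate_model(st, p, g, a, ctl)
  expect_equal(traj$termination, "steady")
  expect_lt(traj$final$T, 1)  # terminates essentially immediately
  # residual drift over 100 explicit steps stays tiny for every equilibrium
  for (lab in c("BS", "GU", "CU", "MU")) {
    eq <- eq_get(low_eqs(), lab)
    s <- uniform_state(g, eq$B1, eq$B2, eq$W)
    res <- rootpattern:::core_integrate(s$B1, s$B2, s$W,
      rootpattern:::core_precomp(p, a), 1e-3, 100, 0)
    drift <- mean(abs(res$B1 - s$B1)) + mean(abs(res$B2 - s$B2)) +
      mean(abs(res$W - s$W))
    expect_lt(drift, 1e-8, label = paste("drift on", lab))
  }
  # determinism: identical seeds give bit-identical trajectories
  gu <- eq_get(low_eqs(), "GU")
  ic1 <- ic_uniform_plus_noise(gu, 1e-3, seed = 99, grid = g)
  ic2 <- ic_uniform_plus_noise(gu, 1e-3, seed = 99, grid = g)
  ctl2 <- solver_control(t_max = 0.5, dt = 1e-3, snapshot_every = 0.25)
  t1 <- integrate_model(ic1, p, g, a, ctl2)
  t2 <- integrate_model(ic2, p, g, a, ctl2)
  expect_identical(t1$final$B1, t2$final$B1)
  expect_identical(t1$final$W, t2$final$W)
})

test_that("unstable bare soil is left and the blow-up guard reports", {
  p <- low_params(P = 1500)
  expect_gt(rootpattern:::bare_soil_growth_rate(p, 1), 0)
  g <- veg_grid(16, 64, ny = 1)
  a <- build_kernel_approx(p, g)
  bs <- list(B1 = 0, B2 = 0, W = p$P / p$N)
  st <- ic_uniform_plus_noise(bs, 1e-4, seed = 3, grid = g)
  st$B2[] <- 0  # shrub-only invasion of bare soil (the sedge is faster)
  ctl <- solver_control(t_max = 6, dt = 1e-3, snapshot_every = 1)
  traj <- integrate_model(st, p, g, a, ctl)
  expect_gt(mean(traj$final$B1), 10 * mean(st$B1))  # perturbation grew
  # gross dt violation must be caught, last valid state returned
  expect_warning(
    tr2 <- integrate_model(st, p, g, a,
      solver_control(t_max = 2, dt = 0.5, snapshot_every = 1)),
    "non-finite")
  expect_equal(tr2$termination, "blowup")
  expect_true(all(is.finite(tr2$final$W)))
})

test_that("clipping is an accounting guard, not a crutch", {
  p <- low_params()
  g <- small_grid_1d()
  a <- build_kernel_approx(p, g)
  cu <- eq_get(low_eqs(), "CU")
  st <- ic_spots(cu, matrix(c(g$Lx / 2, 0), 1), radius = 1,
                 peak = 0.5 * p$K1, grid = g)
  ctl <- solver_control(t_max = 2, dt = 1e-3, snapshot_every = 1, clip = TRUE)
  traj <- integrate_model(st, p, g, a, ctl)
  total_mass <- sum(traj$final$B1 + traj$final$B2 + traj$final$W)
  expect_lt(traj$clipped_mass, 1e-8 * total_mass)
  expect_gt(traj$min_field_value, -1e-6)
})
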