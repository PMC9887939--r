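test_that("parameter defaults reproduce the reference table and validate", {
  p <- veg_params()
  expect_equal(p$E1, 16)
  expect_equal(p$E2, 5)
  expect_equal(unlist(p[c("K1", "K2", "M1", "M2", "N")]),
               c(K1 = 0.7, K2 = 0.35, M1 = 7.05, M2 = 7.05, N = 15))
  expect_equal(unlist(p[c("Lam1", "Lam2", "Gam1", "Gam2")]),
               c(Lam1 = 0.06, Lam2 = 0.16, Gam1 = 15, Gam2 = 5))
  expect_equal(unlist(p[c("Th1", "Th2", "DW", "SG1", "SD1", "SD2")]),
               c(Th1 = 3.125, Th2 = 3.125, DW = 0.5, SG1 = 0.5, SD1 = 0.5,
                 SD2 = 0.01))
  expect_equal(unlist(p[c("Wstar1", "Wstar2", "R1", "R2")]),
               c(Wstar1 = 0.5, Wstar2 = 2, R1 = 0.1, R2 = 0.1))
  expect_error(veg_params(N = 0), "strictly positive")
  expect_error(veg_params(R1 = 1), "0 <= R < 1")
  expect_error(veg_params(E1 = -1), ">= 0")
})

test_that("presets load identically from code and from config files", {
  for (nm in c("default", "low_altitude", "high_altitude", "weak_feedback")) {
    expect_equal(load_preset(nm), preset_params(nm), info = nm)
  }
  p <- preset_params("weak_feedback")
  expect_equal(c(p$E1, p$P, p$K1, p$M1, p$Lam1, p$Gam1, p$SG1, p$SD1,
                 p$Wstar2, p$DW),
               c(2, 1400, 1.75, 9.05, 0.08, 5, 0.01, 0.1, 0.5, 1))
})

test_that("root kernel: values, domain errors, and plane-integral masses", {
  p <- veg_params()
  expect_equal(root_kernel_value(0, 0, p), 1 / (2 * pi * p$SG1^2))
  expect_error(root_kernel_value(-1, 0, p), "r must be")
  expect_error(root_kernel_value(1, -0.1, p), "B must be")

  # quadrature oracle: adaptive radial integral of the plane density
  plane_mass <- function(B) {
    integrate(function(r) root_kernel_value(r, B, p) * 2 * pi * r,
              0, Inf, rel.tol = 1e-10)$value
  }
  expect_equal(plane_mass(0), 1, tolerance = 1e-6)
  expect_equal(plane_mass(0.5), 81, tolerance = 1e-6)  # (1 + 16*0.5)^2
  # 1D analogue carries the same mass
  mass1d <- 2 * integrate(function(r) root_kernel_value(r, 0.3, p, dim = 1),
                          0, Inf, rel.tol = 1e-10)$value
  expect_equal(mass1d, (1 + p$E1 * 0.3)^2, tolerance = 1e-6)
})

test_that("sucker kernel: unit mass, r = 0 value, and Fourier transform", {
  expect_error(sucker_kernel_value(1, -2), "SD must be")
  for (SD in c(0.1, 0.5, 2)) {
    expect_equal(sucker_kernel_value(0, SD), 1 / (2 * pi * SD^2))
    expect_equal(
      integrate(function(r) sucker_kernel_value(r, SD) * 2 * pi * r,
                0, Inf, rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
    # numerical Hankel transform vs the analytic transfer function exp(-SD*k)
    # (finite upper limit; the truncated tail is O(SD/R) ~ 7e-4)
    for (k in c(0.5, 2)) {
      num <- integrate(function(r) sucker_kernel_value(r, SD) *
                         besselJ(k * r, 0) * 2 * pi * r,
                       0, 1500 * SD, rel.tol = 1e-8,
                       subdivisions = 5000L)$value
      expect_equal(num, exp(-SD * k), tolerance = 2e-3)
    }
    # 1D kernel mass
    expect_equal(
      2 * integrate(function(r) sucker_kernel_value(r, SD, dim = 1),
                    0, Inf, rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
  }
})

test_that("local sedge rates match the closed form", {
  p <- veg_params()
  g <- small_grid_2d()
  W <- matrix(50, g$nx, g$ny)
  B2 <- matrix(0, g$nx, g$ny)
  r0 <- local_rates_cyperus(B2, W, p)
  expect_equal(r0$growth, p$Lam2 * W)
  expect_true(all(r0$uptake == 0))
  expect_true(all(local_rates_cyperus(B2 + 0.1, W * 0, p)$growth == 0))
  r <- local_rates_cyperus(B2 + 0.35, W, p)
  expect_equal(r$growth[1, 1], 0.16 * 50 * (1 + 5 * 0.35)^2)  # 60.5
  expect_equal(r$uptake[1, 1], 5 * 0.35 * (1 + 5 * 0.35)^2)   # 13.234375
})

test_that("evaporation rate: bare-soil value, shading bound, pointwise form", {
  p <- veg_params()
  B0 <- matrix(0, 4, 4)
  expect_equal(evaporation_rate(B0, B0, p), matrix(15, 4, 4))
  expect_equal(evaporation_rate(B0 + p$K1, B0, p)[1, 1], 0.9 * p$N)
  set.seed(7)
  B1 <- matrix(runif(16, 0, p$K1), 4, 4)
  B2 <- matrix(runif(16, 0, p$K2), 4, 4)
  L <- evaporation_rate(B1, B2, p)
  expect_equal(L, p$N * (1 - p$R1 * B1 / p$K1 - p$R2 * B2 / p$K2))
  expect_true(all(L >= p$N * (1 - p$R1 - p$R2)))
})

test_that("sucker growth: water gating, unit kernel mass, nonlocal reach", {
  p <- low_params()
  g <- small_grid_2d()
  a <- build_kernel_approx(p, g)
  B <- smooth_field(g, 0.5, seed = 1)
  W0 <- matrix(0, g$nx, g$ny)
  expect_true(all(sucker_growth(B, W0, 1, p, a) == 0))
  expect_error(sucker_growth(B, W0 - 1, 1, p, a), ">= 0")
  # uniform fields: kernel mass is exactly 1
  Bu <- matrix(0.2, g$nx, g$ny); Wu <- matrix(8, g$nx, g$ny)
  D1 <- sucker_growth(Bu, Wu, 1, p, a)
  expect_equal(D1[2, 3], p$Th1 * 8 / (8 + p$Wstar1) * 0.2, tolerance = 1e-12)
  D2 <- sucker_growth(Bu, Wu, 2, p, a)
  expect_equal(D2[1, 1], p$Th2 * 8 / (8 + p$Wstar2) * 0.2, tolerance = 1e-12)

  # localized spike reaches far: compare with direct quadrature of the
  # periodized fat-tailed kernel at a lag of 3 m = 6 * SD1
  Bs <- matrix(0, g$nx, g$ny); Bs[1, 1] <- 1
  Wu1 <- matrix(1, g$nx, g$ny)
  D <- sucker_growth(Bs, Wu1, 1, p, a)
  lag <- 12  # cells along x -> 3 m
  far <- D[1 + lag, 1]
  expect_gt(far, 0)  # response at distance >> SD1
  kv <- 0
  for (sx in c(-1, 0, 1) * g$Lx) for (sy in c(-1, 0, 1) * g$Ly)
    kv <- kv + sucker_kernel_value(sqrt((lag * g$dx + sx)^2 + sy^2), p$SD1)
  direct <- p$Th1 * 1 / (1 + p$Wstar1) * kv * g$dA
  # spectral evaluation truncates the fat tail at the grid Nyquist scale, so
  # agreement is approximate away from the source
  expect_equal(far, direct, tolerance = 0.1)
})

test_that("rhs: bare-soil equilibrium is exact; water budget closes; no
           negative biomass generation at the zero boundary", {
  p <- low_params()
  g <- small_grid_2d()
  a <- build_kernel_approx(p, g)
  bs <- uniform_state(g, 0, 0, p$P / p$N)
  r <- veg_rhs(bs, p, g, a)
  expect_equal(max(abs(r$dB1)), 0)
  expect_equal(max(abs(r$dB2)), 0)
  expect_lt(max(abs(r$dW)), 1e-10)

  # arbitrary state: mean dW equals mean(P - L W - W sum(G_W)); the spectral
  # Laplacian integrates to zero on the periodic domain
  st <- veg_state(smooth_field(g, 0.6, 2), smooth_field(g, 0.3, 3),
                  smooth_field(g, 10, 4, floor = 2), grid = g)
  r <- veg_rhs(st, p, g, a)
  L <- evaporation_rate(st$B1, st$B2, p)
  sink <- nonlocal_uptake(st$B1, a, p) + local_rates_cyperus(st$B2, st$W, p)$uptake
  expect_equal(mean(r$dW), mean(p$P - L * st$W - st$W * sink),
               tolerance = 1e-10)

  # B_i = 0 with biomass elsewhere: dB_i equals the (nonnegative) sucker term
  st0 <- st
  st0$B1[3, ] <- 0
  r0 <- veg_rhs(st0, p, g, a)
  D1 <- sucker_growth(st0$B1, st0$W, 1, p, a)
  expect_equal(r0$dB1[3, ], D1[3, ])
  expect_true(all(r0$dB1[3, ] >= 0))
})

test_that("local-limit equivalence: narrow root kernel reproduces the
           algebraic rates on uniform fields", {
  g <- small_grid_2d()
  p <- low_params(SG1 = g$dx / 8)  # much narrower than the grid
  a <- build_kernel_approx(p, g)
  b <- 0.33; w <- 12
  Gb <- nonlocal_growth(matrix(w, g$nx, g$ny), matrix(b, g$nx, g$ny), a, p)
  Gw <- nonlocal_uptake(matrix(b, g$nx, g$ny), a, p)
  expect_equal(Gb[1, 1], p$Lam1 * w * (1 + p$E1 * b)^2, tolerance = 1e-2)
  expect_equal(Gw[1, 1], p$Gam1 * b * (1 + p$E1 * b)^2, tolerance = 1e-2)
})

test_that("sedge dispersal: the local switch leaves uniform equilibria
           unchanged", {
  p_loc <- low_params(cyperus_local = TRUE)
  eqs_nl <- low_eqs()
  eqs_loc <- uniform_equilibria(p_loc)
  labs <- function(eqs) sort(vapply(eqs, `[[`, "", "label"))
  expect_equal(labs(eqs_loc), labs(low_eqs()))
  for (lab in c("BS", "GU", "CU", "MU")) {
    a <- eq_get(eqs_nl, lab); b <- eq_get(eqs_loc, lab)
    expect_equal(c(a$B1, a$B2, a$W), c(b$B1, b$B2, b$W), tolerance = 1e-9)
  }
})
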