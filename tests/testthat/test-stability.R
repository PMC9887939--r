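test_that("uniform equilibria: bare soil exact, residuals tiny, all four
           states present at the low-altitude preset", {
  p <- low_params()
  eqs <- low_eqs()
  labs <- vapply(eqs, `[[`, "", "label")
  expect_setequal(unique(labs), c("BS", "GU", "CU", "MU"))
  bs <- eq_get(eqs, "BS")
  expect_identical(c(bs$B1, bs$B2), c(0, 0))
  expect_identical(bs$W, p$P / p$N)
  for (eq in eqs) expect_lt(eq$residual, 1e-10)
  # PDE-relaxation oracle: integrating from near GU converges to GU values
  gu <- eq_get(eqs, "GU")
  g <- veg_grid(16, 64, ny = 1)
  a <- build_kernel_approx(p, g)
  st <- uniform_state(g, gu$B1 * 1.05, 0, gu$W * 0.95)
  traj <- integrate_model(st, p, g, a,
    solver_control(t_max = 40, dt = 1e-3, snapshot_every = 5,
                   steady_tol = 1e-12))
  expect_equal(mean(traj$final$B1), gu$B1, tolerance = 1e-5)
  expect_equal(mean(traj$final$W), gu$W, tolerance = 1e-5)
})

test_that("bare-soil invasibility eigenvalue matches the closed-form
           linearization", {
  p <- preset_params("default")  # P = 1500
  W <- p$P / p$N
  expect_equal(W, 100)
  closed <- p$Lam1 * W - p$M1 + p$Th1 * W / (W + p$Wstar1)
  expect_gt(closed, 0)  # bare soil invasible by the shrub
  bs <- eq_get(uniform_equilibria(p), "BS")
  J <- uniform_jacobian(bs, p)
  expect_equal(J[1, 1], closed, tolerance = 1e-6)
  # and via finite differences of the discretized rhs (uniform mode)
  M0 <- rootpattern:::mode_operator(c(0, 0, W), p, 0)
  expect_equal(M0[1, 1], closed, tolerance = 1e-6)
})

test_that("dispersion relation: zero-mode consistency across branches and
           P values", {
  p <- low_params()
  for (P in c(800, 1000, 1200, 1500, 1800)) {
    pp <- p; pp$P <- P
    eqs <- uniform_equilibria(pp)
    for (eq in eqs) {
      J <- uniform_jacobian(eq, pp)
      lam_J <- max(Re(eigen(J, only.values = TRUE)$values))
      M0 <- rootpattern:::mode_operator(c(eq$B1, eq$B2, eq$W), pp, 0)
      lam_0 <- max(Re(eigen(M0, only.values = TRUE)$values))
      expect_equal(lam_0, lam_J, tolerance = 1e-6,
                   label = sprintf("lambda(0), %s at P=%g", eq$label, P))
    }
  }
})

test_that("bare-soil dispersion matches the closed-form decoupled rates", {
  # at B = 0 the biomass modes decouple from w and from each other:
  # lambda_i(k) = Lam_i*W - M_i + Th_i*W/(W+Wstar_i)*phihat_i(k).
  # The root-kernel transform does NOT enter: the growth convolution acts on
  # the uniform W field (mass 1 at B = 0), only the fat-tailed
  # sucker/dispersal kernel filters the biomass mode.
  p <- low_params(P = 1500)
  W <- p$P / p$N
  ks <- c(0.3, 1, 2.5)
  dc <- dispersion_relation(list(B1 = 0, B2 = 0, W = W), p, ks)
  for (i in seq_along(ks)) {
    k <- ks[i]
    lam1 <- p$Lam1 * W - p$M1 + p$Th1 * W / (W + p$Wstar1) * exp(-p$SD1 * k)
    lam2 <- p$Lam2 * W - p$M2 + p$Th2 * W / (W + p$Wstar2) * exp(-p$SD2 * k)
    evs <- sort(Re(dc$sigma[, i]), decreasing = TRUE)
    expect_true(any(abs(evs - lam1) < 1e-4 * max(1, abs(lam1))),
                label = sprintf("shrub BS rate at k=%g", k))
    expect_true(any(abs(evs - lam2) < 1e-4 * max(1, abs(lam2))),
                label = sprintf("sedge BS rate at k=%g", k))
  }
})

test_that("GU dispersion at the low-altitude preset has an interior maximum
           that crosses zero as P decreases", {
  p <- low_params()
  kg <- seq(0.05, 3, length.out = 50)
  lam_max <- function(P) {
    pp <- p; pp$P <- P
    eq <- eq_get(uniform_equilibria(pp), "GU")
    dc <- dispersion_relation(eq, pp, kg)
    i <- which.max(dc$lambda)
    list(lam = dc$lambda[i], k = dc$k[i])
  }
  lo <- lam_max(1000)
  expect_gt(lo$lam, 0)      # unstable to a finite-k mode
  expect_gt(lo$k, 0.2)      # genuinely interior (not the uniform mode)
})

test_that("turing_threshold honours its bisection contract", {
  p <- low_params()
  kg <- seq(0.1, 2, length.out = 30)
  tp1 <- turing_threshold(p, "GU", 1000, 2600, tol = 8, k_grid = kg)
  expect_false(is.null(tp1))
  tp2 <- turing_threshold(p, "GU", 1000, 2600, tol = 0.8, k_grid = kg)
  expect_lt(abs(tp2$P_c - tp1$P_c), 8)
  expect_gt(tp2$k_c, 0)
  expect_true(all(tp2$conditions))
  # no sign change in the bracket -> no Turing point
  expect_null(turing_threshold(p, "GU", 600, 900, tol = 8, k_grid = kg))
})

test_that("branch scan: BS stability flips where the closed-form growth
           rate crosses zero, and the GU/CU/MU topology is dP-robust", {
  p <- low_params()
  # closed-form oracle for the BS destabilization threshold of species 2
  # (the first species to invade bare soil as P rises)
  f <- function(P) {
    W <- P / p$N
    max(p$Lam1 * W - p$M1 + p$Th1 * W / (W + p$Wstar1),
        p$Lam2 * W - p$M2 + p$Th2 * W / (W + p$Wstar2))
  }
  P_star <- uniroot(f, c(100, 2000), tol = 1e-10)$root
  d <- scan_branches(p, c(P_star - 40, P_star + 40), dP = 10,
                     branches = "BS")
  bs <- d[d$branch == "BS", ]
  flip <- bs$P[which(diff(bs$stable_uniform) != 0)]
  expect_true(length(flip) == 1 && abs(flip + 10 / 2 - P_star) <= 10 / 2 + 1)
  d2 <- scan_branches(p, c(P_star - 40, P_star + 40), dP = 5, branches = "BS")
  bs2 <- d2[d2$branch == "BS", ]
  flip2 <- bs2$P[which(diff(bs2$stable_uniform) != 0)]
  expect_lt(abs(flip2 - flip), 10 + 1e-9)  # topology robust to halving dP
})
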