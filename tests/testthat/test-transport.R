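test_that("closed-form profile honors boundaries, vertex and a hand calculation", {
  tp <- transport_params(D_cm2_yr = 900, phi = 0.8, FF = 1.5625, Z_m = 70)
  P <- 2e-15
  expect_equal(steady_state_profile(P, tp, 0), 0)
  expect_equal(steady_state_profile(P, tp, 70), 0)
  vertex <- P * tp$phi * tp$FF * tp$Z_cm^2 / (8 * tp$D)
  expect_equal(steady_state_profile(P, tp, 35), vertex, tolerance = 1e-12)
  x <- seq(0, 70, by = 0.7)
  prof <- steady_state_profile(P, tp, x)
  expect_true(all(prof <= vertex + 1e-30))
  # P*phi*F/D = 8 per cm^2, Z = 1 cm: C(0.5 cm) = 0.5*8*(0.5 - 0.25) = 1
  tp1 <- transport_params(D_cm2_yr = 1, phi = 0.5, FF = 2, Z_m = 0.01)
  expect_equal(steady_state_profile(8, tp1, 0.005), 1.0, tolerance = 1e-12)
  expect_error(steady_state_profile(P, tp, 80), "outside")
})

test_that("profiles scale linearly in P and inversely in D", {
  tp <- transport_params(900, 0.8, 1.5625, 70)
  tp2 <- transport_params(1800, 0.8, 1.5625, 70)
  x <- seq(0, 70, length.out = 31)
  expect_equal(steady_state_profile(4e-15, tp, x),
               2 * steady_state_profile(2e-15, tp, x), tolerance = 1e-12)
  expect_equal(steady_state_profile(2e-15, tp2, x),
               steady_state_profile(2e-15, tp, x) / 2, tolerance = 1e-12)
})

test_that("integral balance: column production equals boundary fluxes out", {
  tp <- transport_params(900, 0.8, 1.5625, 70)
  P <- 3e-15
  b <- P * tp$phi * tp$FF / tp$D
  dCdx_top <- b * tp$Z_cm / 2                 # C'(0), closed form
  dCdx_bot <- -b * tp$Z_cm / 2                # C'(Z)
  flux_out <- (tp$D / (tp$phi * tp$FF)) * (dCdx_top - dCdx_bot)
  expect_equal(flux_out, P * tp$Z_cm, tolerance = 1e-12)
})

test_that("finite-difference solution matches the analytic uniform profile", {
  u <- data.frame(thickness_m = 70, P_pw = 1e-15, phi = 0.8, FF = 1.5625, D = 900)
  tp <- transport_params(900, 0.8, 1.5625, 70)
  np <- numeric_profile(u, n_nodes = 1e4)
  an <- steady_state_profile(1e-15, tp, np$x_m)
  expect_lt(max(abs(np$conc - an)) / max(an), 1e-6)
  # zero production -> zero profile
  z <- numeric_profile(data.frame(thickness_m = 10, P_pw = 0, phi = 0.8,
                                  FF = 2, D = 900), 101)
  expect_true(all(z$conc == 0))
  expect_error(numeric_profile(u, n_nodes = 2), "n_nodes")
})

test_that("finite-difference solver converges at second order on a smooth source", {
  u <- data.frame(thickness_m = 80, P_pw = 0, phi = 0.8, FF = 1.5625, D = 900)
  truth <- function(x_m) {
    x <- x_m * 100; Z <- 8000
    (0.8 * 1.5625 * 1e-15 / 900) * (Z / pi)^2 * sin(pi * x / Z)
  }
  Pf <- function(z_m) 1e-15 * sin(pi * z_m / 80)
  err <- vapply(c(101, 201, 401), function(n) {
    np <- numeric_profile(u, n, P_fun = Pf)
    max(abs(np$conc - truth(np$x_m))) / max(truth(np$x_m))
  }, numeric(1))
  ratios <- err[-3] / err[-1]
  expect_true(all(ratios > 3.5 & ratios < 4.5))
})

test_that("two-layer closed form degenerates, is continuous, and matches the solver", {
  # identical layers reduce to the single-layer solution pointwise
  same <- data.frame(thickness_m = c(30, 40), P_pw = 2e-15, phi = 0.8,
                     FF = 1.5625, D = 900)
  tp <- transport_params(900, 0.8, 1.5625, 70)
  x <- seq(0, 70, length.out = 141)
  expect_equal(two_layer_profile(same, x), steady_state_profile(2e-15, tp, x),
               tolerance = 1e-10)
  # continuity of concentration and of -(D/(phi F)) dC/dx at the interface
  lay <- data.frame(thickness_m = c(30, 50), P_pw = c(2e-15, 5e-16),
                    phi = c(0.8, 0.6), FF = c(1.5, 2.5), D = c(900, 500))
  a <- 30; eps <- 1e-7
  cL <- two_layer_profile(lay, a - eps); cR <- two_layer_profile(lay, a + eps)
  expect_lt(abs(cL - cR) / max(abs(c(cL, cR))), 1e-8)
  k <- lay$D / (lay$phi * lay$FF)
  dL <- (two_layer_profile(lay, a) - two_layer_profile(lay, a - eps)) / (eps * 100)
  dR <- (two_layer_profile(lay, a + eps) - two_layer_profile(lay, a)) / (eps * 100)
  expect_equal(k[1] * dL, k[2] * dR, tolerance = 1e-4)
  # numeric oracle with the interface on a grid node
  np <- numeric_profile(lay, n_nodes = 8001)
  tl <- two_layer_profile(lay, np$x_m)
  expect_lt(max(abs(np$conc - tl)) / max(tl), 1e-6)
  expect_error(two_layer_profile(same[1, ], x), "exactly 2")
})

test_that("profile comparison censors sub-detection values and flags consumption", {
  meas <- data.frame(depth_m = 1:10, H2_nM = rep(1, 10),
                     detection_limit_nM = 2)
  expd <- data.frame(x_m = 0:11, conc = rep(1000, 12))
  cmp <- compare_profiles(meas, expd)
  expect_true(all(cmp$table$censored))
  expect_equal(cmp$table$ratio, rep(500, 10))       # bounded by DL, not by 1 nM
  expect_true(cmp$consumption_flag)
  # measured == expected: ratios 1, no flag
  meas2 <- data.frame(depth_m = 1:10, H2_nM = 100, detection_limit_nM = 2)
  expd2 <- data.frame(x_m = 0:11, conc = 100)
  cmp2 <- compare_profiles(meas2, expd2)
  expect_equal(cmp2$table$ratio, rep(1, 10))
  expect_false(cmp2$consumption_flag)
  # three orders of magnitude
  cmp3 <- compare_profiles(data.frame(depth_m = 5, H2_nM = 1,
                                      detection_limit_nM = 0.5), expd)
  expect_equal(cmp3$orders_of_magnitude, 3, tolerance = 1e-12)
  expect_error(compare_profiles(data.frame(depth_m = 100, H2_nM = 1), expd),
               "common depth")
})

test_that("H2 diffusivity increases with temperature and is overridable", {
  expect_gt(D_H2(20), D_H2(2))
  expect_equal(D_H2(2) / radh2_constants$sec_per_yr * 1e6, 25.9 + 0.81 * 2,
               tolerance = 1e-12)
})
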