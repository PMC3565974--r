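# Curve fitting: equilibrium detection, round trips at reduced problem
# sizes, degenerate inputs. (Full-protocol recovery at the published group
# means is exercised in test-acceptance.R.)

make_hold_curve <- function(t, force, strain = 0.05) {
  geo <- disc_geometry()
  new_mech_curve(t, force, rep(strain * geo$thickness, length(t)), geo,
                 data.frame(t = c(0, t[1], max(t)), strain = c(0, strain, strain)),
                 test = "unconfined")
}

test_that("equilibrium detection matches the analytic crossing for exponential decay", {
  thr_nps <- 0.1 * GRAM_FORCE_N / 60
  tau <- 2000; a <- 0.5
  t <- seq(5, 12000, by = 5)
  curve <- make_hold_curve(t, a * exp(-t / tau))
  # |dF/dt| = (a/tau) e^{-t/tau} = thr  =>  t* = tau log(a / (tau thr))
  t_star <- tau * log(a / (tau * thr_nps))
  eq <- detect_equilibrium(curve)
  expect_true(eq$met)
  expect_lt(abs(eq$time - t_star), 15)   # within two samples + window bias
})

test_that("constant force is at equilibrium from the first full window", {
  t <- seq(5, 2000, by = 5)
  curve <- make_hold_curve(t, rep(1, length(t)))
  eq <- detect_equilibrium(curve)
  expect_true(eq$met)
  expect_lte(eq$time, t[1] + 300 / 2 + 5)
})

test_that("monotonically rising force never meets the criterion", {
  t <- seq(5, 2000, by = 5)
  curve <- make_hold_curve(t, 0.01 * t)
  eq <- detect_equilibrium(curve)
  expect_false(eq$met)
  expect_equal(eq$index, length(curve$t))
})

test_that("short segments are flagged", {
  t <- seq(5, 100, by = 5)
  curve <- make_hold_curve(t, exp(-t / 50))
  eq <- detect_equilibrium(curve)
  expect_true(eq$short_segment)
})

test_that("unconfined fit recovers all generator parameters (noiseless)", {
  truth <- mech_truth()
  curve <- simulate_unconfined_test(truth, n_ramps = 3L)
  fit <- fit_unconfined(curve, n_starts = 1L)
  expect_lt(abs(fit$e_young - truth$e_young) / truth$e_young, 0.01)
  expect_lt(abs(fit$k_r - truth$k_r) / truth$k_r, 0.05)
  expect_lt(abs(fit$nu - truth$nu), 0.05 * 0.5)
  expect_lt(abs(fit$c_visc - truth$c_visc) / truth$c_visc, 0.05)
  expect_lt(abs(fit$mu_visc - truth$mu_visc) / truth$mu_visc, 0.05)
  expect_true(fit$diagnostics$stage2_converged)
})

test_that("unconfined fit with c = 0 returns c near 0 and recovers (k_r, nu)", {
  truth <- mech_truth(c_visc = 0, mu_visc = 0.001)
  curve <- simulate_unconfined_test(truth, n_ramps = 3L)
  fit <- fit_unconfined(curve, n_starts = 1L)
  expect_lt(fit$c_visc, 0.02)
  expect_lt(abs(fit$k_r - truth$k_r) / truth$k_r, 0.05)
  expect_lt(abs(fit$nu - truth$nu), 0.05 * 0.5)
})

test_that("equilibrium-only unconfined data flag stage 2 as unidentifiable", {
  geo <- disc_geometry()
  # pure elastic staircase: force = E * strain * area at every instant
  E <- 0.02
  sched <- data.frame(t = c(0, 60, 1000, 1060, 2000),
                      strain = c(0, 0.05, 0.05, 0.10, 0.10))
  t <- seq(5, 2000, by = 5)
  strain <- approx(sched$t, sched$strain, xout = t)$y
  force <- E * MPA * strain * geo$area_m2
  curve <- new_mech_curve(t, force, strain * geo$thickness, geo, sched,
                          "unconfined")
  fit <- fit_unconfined(curve)
  expect_true(fit$diagnostics$stage2_unidentifiable)
  expect_equal(fit$e_young, E, tolerance = 1e-6)
  expect_true(is.na(fit$k_r))
})

test_that("confined fit on linear data returns beta and M within 0.2 of zero", {
  truth <- mech_truth(beta = 0, m_perm = 0)
  curve <- simulate_confined_test(truth, n_ramps = 2L, n_nodes = 61L,
                                  max_hold = 2400)
  fit <- fit_confined(curve, n_nodes = 61L, n_starts = 1L, maxiter = 30L)
  expect_lt(abs(fit$h_a0 - truth$h_a0) / truth$h_a0, 0.05)
  expect_lt(abs(fit$k_0 - truth$k_0) / truth$k_0, 0.05)
  expect_lt(abs(fit$beta), 0.2)
  expect_lt(abs(fit$m_perm), 0.2)
})

test_that("time-rescaled confined curves give the same modulus and halved permeability", {
  truth <- mech_truth(beta = 0, m_perm = 0)
  curve <- simulate_confined_test(truth, n_ramps = 2L, n_nodes = 61L,
                                  max_hold = 2400)
  slowed <- new_mech_curve(2 * curve$t, curve$force, curve$displacement,
                           curve$geometry,
                           transform(curve$schedule, t = 2 * t),
                           curve$test)
  fit <- fit_confined(slowed, n_nodes = 61L, n_starts = 1L, maxiter = 30L)
  expect_lt(abs(fit$h_a0 - truth$h_a0) / truth$h_a0, 0.05)
  expect_lt(abs(fit$k_0 - truth$k_0 / 2) / (truth$k_0 / 2), 0.05)
})

test_that("single-ramp confined data yield a linear-only fit with flags", {
  truth <- mech_truth(beta = 0, m_perm = 0)
  curve <- simulate_confined_test(truth, n_ramps = 1L, n_nodes = 61L,
                                  max_hold = 2400)
  fit <- suppressWarnings(
    fit_confined(curve, n_nodes = 61L, n_starts = 1L, maxiter = 30L))
  expect_true(is.na(fit$beta))
  expect_true(fit$diagnostics$nonlinearity_unidentifiable)
  expect_lt(abs(fit$h_a0 - truth$h_a0) / truth$h_a0, 0.05)
})

test_that("instant-equilibrium confined data flag the permeability", {
  geo <- disc_geometry()
  sched <- data.frame(t = c(0, 60, 1000), strain = c(0, 0.05, 0.05))
  t <- seq(5, 1000, by = 5)
  strain <- approx(sched$t, sched$strain, xout = t)$y
  force <- 0.12 * MPA * strain * geo$area_m2
  curve <- new_mech_curve(t, force, strain * geo$thickness, geo, sched,
                          "confined")
  fit <- fit_confined(curve)
  expect_true(fit$diagnostics$k0_unidentifiable)
  expect_true(is.na(fit$k_0))
})
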