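# Forward solvers: closed-form limits, oracle agreement, conservation.

test_that("linear confined series reaches the drained equilibrium H_A0 * eps", {
  geo <- disc_geometry()
  sched <- data.frame(t = c(0, 60, 3e5), strain = c(0, 0.05, 0.05))
  s <- confined_forward_linear(0.12, 15, geo, sched, c(1e4, 3e5))
  expect_equal(s[2], 0.12 * 0.05, tolerance = 1e-6)
})

test_that("linear confined response obeys the permeability/time rescaling identity", {
  geo <- disc_geometry()
  sched1 <- data.frame(t = c(0, 60, 2000), strain = c(0, 0.05, 0.05))
  t1 <- seq(5, 2000, by = 15)
  sched2 <- sched1; sched2$t <- 2 * sched1$t
  s1 <- confined_forward_linear(0.12, 15, geo, sched1, t1)
  s2 <- confined_forward_linear(0.12, 7.5, geo, sched2, 2 * t1)
  expect_equal(s2, s1, tolerance = 1e-9)
})

test_that("nonlinear FD solver matches the linear series at beta = M = 0", {
  geo <- disc_geometry()
  sched <- data.frame(t = c(0, 60, 1500), strain = c(0, 0.05, 0.05))
  tt <- seq(2, 1500, by = 10)
  s_lin <- confined_forward_linear(0.12, 15, geo, sched, tt)
  s_fd <- confined_forward_nonlinear(0.12, 15, 0, 0, geo, sched, tt)
  expect_lt(max(abs(s_fd - s_lin)) / max(abs(s_lin)), 0.01)
  # refined grid: 0.1%
  s_fd2 <- confined_forward_nonlinear(0.12, 15, 0, 0, geo, sched, tt,
                                      n_nodes = 401L)
  expect_lt(max(abs(s_fd2 - s_lin)) / max(abs(s_lin)), 0.001)
})

test_that("nonlinear equilibrium equals the constitutive quadrature", {
  geo <- disc_geometry()
  sched <- data.frame(t = c(0, 60, 8000), strain = c(0, 0.05, 0.05))
  s <- confined_forward_nonlinear(0.12, 15, 0.5, 0.5, geo, sched, 8000)
  expect_equal(s, 0.12 * (1 - exp(-0.5 * 0.05)) / 0.5, tolerance = 1e-5)
})

test_that("doubling the FD grid changes the curve by < 0.2%", {
  geo <- disc_geometry()
  sched <- data.frame(t = c(0, 60, 800), strain = c(0, 0.05, 0.05))
  tt <- seq(10, 800, by = 10)
  a <- confined_forward_nonlinear(0.12, 15, 0.5, 0.5, geo, sched, tt,
                                  n_nodes = 101L)
  b <- confined_forward_nonlinear(0.12, 15, 0.5, 0.5, geo, sched, tt,
                                  n_nodes = 201L)
  expect_lt(max(abs(a - b)) / max(abs(a)), 0.002)
})

test_that("FD solver conserves fluid volume: strain integral tracks the platen", {
  geo <- disc_geometry()
  sched <- data.frame(t = c(0, 60, 600), strain = c(0, 0.05, 0.05))
  tt <- c(30, 60, 300, 600)
  s <- confined_forward_nonlinear(0.12, 15, 0.5, 0.5, geo, sched, tt,
                                  full = TRUE)
  fields <- attr(s, "fields"); widths <- attr(s, "widths")
  applied <- -approx(sched$t, sched$strain, xout = tt)$y * geo$thickness_m
  swept <- as.vector(fields %*% widths)
  expect_equal(swept, applied, tolerance = 5e-3)
})

test_that("unconfined model reproduces the instantaneous and drained limits", {
  geo <- disc_geometry()
  E <- 0.019; nu <- 0.1
  mu_s <- E / (2 * (1 + nu))
  ramps <- data.frame(t0 = 0, duration = 0.2, d_strain = 0.05)
  s <- unconfined_forward(E, nu, 32, 0, 0.57, geo, ramps, c(0.2, 5e5))
  expect_equal(s[1], 3 * mu_s * 0.05, tolerance = 2e-3)
  expect_equal(s[2], E * 0.05, tolerance = 1e-9)
})

test_that("unconfined solver converges under radial grid refinement", {
  geo <- disc_geometry()
  ramps <- data.frame(t0 = 0, duration = 60, d_strain = 0.05)
  tt <- c(30, 60, 300, 1000, 3000)
  a <- unconfined_forward(0.019, 0.1, 32, 0.3, 0.57, geo, ramps, tt,
                          n_nodes = 40L)
  b <- unconfined_forward(0.019, 0.1, 32, 0.3, 0.57, geo, ramps, tt,
                          n_nodes = 120L)
  expect_lt(max(abs(a - b)) / max(abs(a)), 0.005)
})

test_that("viscoelastic overlay leaves the equilibrium untouched and scales the transient", {
  geo <- disc_geometry()
  ramps <- data.frame(t0 = 0, duration = 60, d_strain = 0.05)
  tt <- c(61, 1e6)
  base <- unconfined_forward(0.019, 0.1, 32, 0, 0.57, geo, ramps, tt)
  ov <- unconfined_forward(0.019, 0.1, 32, 0.5, 0.57, geo, ramps, tt)
  expect_equal(ov[2], base[2], tolerance = 1e-9)
  expect_gt(ov[1], base[1])
})

test_that("Darcy record inverts exactly and scales linearly", {
  geo <- disc_geometry()
  rec <- simulate_darcy_test(10, geo, delta_p = 40e3, fluid_viscosity = 1e-3)
  k <- darcy_permeability(rec)
  expect_equal(k$k, 10e-15)
  expect_equal(k$k_report, 10)
  rec2 <- simulate_darcy_test(20, geo, delta_p = 40e3)
  expect_equal(rec2$q, 2 * rec$q)
  # direct arithmetic on a published-protocol flow rate
  man <- list(q = 5.556e-12, delta_p = 4e4, length = 1.6e-3,
              area = 1.9635e-5, fluid_viscosity = 1e-3)
  expect_equal(darcy_permeability(man)$k, 1.131908e-17, tolerance = 1e-6)
  bad <- rec; bad$delta_p <- 0
  expect_error(darcy_permeability(bad), "delta_p")
})
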