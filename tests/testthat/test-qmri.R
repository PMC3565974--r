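# Relaxometry, MT and diffusion estimators: exactness on noiseless data,
# agreement with brute-force oracles, and rotation invariance.

test_that("T1 fit recovers truth within 0.5% across the physiological range", {
  p <- acquisition_protocol()
  for (t1 in c(200, 706, 1140, 2000, 3000)) {
    tt <- tissue_truth(t1, t2 = min(150, t1 / 2), mtr = 0.3,
                       tensor = tensor_from_md_fa(1.5e-3, 0.1))
    f <- fit_t1(simulate_ir_series(tt, p), p)
    expect_lt(abs(f$t1 - t1) / t1, 0.005)
    expect_true(f$diagnostics$converged)
  }
})

test_that("T1 fit equals the 2-D grid-search oracle", {
  set.seed(7)
  p <- acquisition_protocol()
  for (i in 1:3) {
    t1 <- stats::runif(1, 400, 2500); s0 <- stats::runif(1, 500, 2000)
    tt <- tissue_truth(t1, 100, 0.3, tensor_from_md_fa(1.5e-3, 0.1), s0 = s0)
    series <- simulate_ir_series(tt, p)
    oracle <- t1_grid_oracle(series, p)
    f <- fit_t1(series, p)
    expect_lt(abs(f$t1 - oracle$t1), 0.2)   # within the refined grid pitch
    expect_lt(abs(f$s0 - s0) / s0, 1e-6)
  }
})

test_that("T1 fit handles magnitude data and flags degenerate series", {
  p <- acquisition_protocol()
  tt <- np_truth()
  f <- fit_t1(simulate_ir_series(tt, p, magnitude = TRUE), p, magnitude = TRUE)
  expect_lt(abs(f$t1 - 1140) / 1140, 0.005)
  flat <- fit_t1(new_signal_series("IR", p$inversion_times,
                                   rep(1000, 15), p), p)
  expect_true(flat$diagnostics$degenerate)
  expect_true(is.na(flat$t1))
})

test_that("T2 log-linear fit is exact on noiseless decay", {
  f <- fit_t2(simulate_echo_series(np_truth()))
  expect_equal(f$t2, 124, tolerance = 1e-12)
  expect_equal(f$si0, 1000, tolerance = 1e-9)
})

test_that("two-point T2 fit gives the closed form 15/ln 2", {
  p <- acquisition_protocol(echo_times_t2 = c(15, 30))
  s <- new_signal_series("ECHO", c(15, 30), c(100, 50), p)
  expect_equal(fit_t2(s)$t2, 15 / log(2), tolerance = 1e-12)
})

test_that("T2 fit excludes non-positive points and flags non-decaying data", {
  p <- acquisition_protocol()
  y <- echo_signal(p$echo_times_t2, 124, 1000)
  y[3] <- 0
  s <- new_signal_series("ECHO", p$echo_times_t2, y, p)
  expect_warning(f <- fit_t2(s), "excluding")
  expect_equal(f$t2, 124, tolerance = 1e-10)
  expect_equal(f$diagnostics$n_excluded, 1L)
  const <- new_signal_series("ECHO", p$echo_times_t2, rep(5, 10), p)
  expect_true(fit_t2(const)$diagnostics$nondecaying)
})

test_that("MTR computation matches the defining ratio", {
  expect_equal(compute_mtr(1000, 660), 0.34)
  expect_equal(compute_mtr(5, 5), 0)
  expect_equal(compute_mtr(7, 0), 1)
  expect_error(compute_mtr(0, 1), "m0")
  tt <- np_truth()
  pair <- simulate_mt_pair(tt)
  expect_equal(compute_mtr(pair["m0"], pair["ms"]), c(m0 = tt$mtr))
})

test_that("tensor fit equals the normal-equations oracle and recovers truth", {
  set.seed(13)
  p <- acquisition_protocol()
  for (i in 1:4) {
    R <- random_rotation()
    ev <- sort(stats::runif(3, 0.3e-3, 2.5e-3), decreasing = TRUE)
    D <- R %*% diag(ev) %*% t(R)
    tt <- tissue_truth(1000, 100, 0.3, D)
    fit <- fit_diffusion_tensor(simulate_dwi_series(tt, p), p)
    expect_equal(fit$eigenvalues, ev, tolerance = 1e-10)
    # independent oracle: explicit normal equations
    g <- p$gradient_dirs
    X <- p$b_value * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                           2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                           2 * g[, 2] * g[, 3])
    rhs <- -log(dwi_signal(g, D, p$b_value, tt$s0) / tt$s0)
    d <- solve(crossprod(X), crossprod(X, rhs))
    D_or <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3)
    expect_equal(fit$tensor, D_or, tolerance = 1e-10)
  }
})

test_that("isotropic diffusion is recovered to machine precision", {
  p <- acquisition_protocol()
  tt <- tissue_truth(1000, 100, 0.3, 1.5e-3 * diag(3))
  fit <- fit_diffusion_tensor(simulate_dwi_series(tt, p), p)
  expect_equal(fit$tensor, 1.5e-3 * diag(3), tolerance = 1e-12)
})

test_that("underdetermined direction sets are rejected", {
  p5 <- acquisition_protocol(gradient_dirs = gradient_scheme(15)[1:6, ])
  tt <- np_truth()
  s <- simulate_dwi_series(tt, p5)
  s$y <- s$y[1:6]; s$x <- s$x[1:6]   # b=0 plus only 5 directions
  p_bad <- p5; p_bad$gradient_dirs <- p5$gradient_dirs[1:5, ]
  expect_error(fit_diffusion_tensor(s, p_bad), "underdetermined|6 usable")
})

test_that("scalar metrics match closed forms", {
  m <- tensor_metrics(c(3, 2, 1))
  expect_equal(m$adc, 2)
  expect_equal(m$fa, sqrt(6 / 28), tolerance = 1e-12)
  expect_equal(tensor_metrics(c(1, 0, 0))$fa, 1)
  expect_equal(tensor_metrics(c(1, 0, 0))$adc, 1 / 3)
  expect_equal(tensor_metrics(c(2, 2, 2))$fa, 0)
  expect_error(tensor_metrics(c(0, 0, 0)), "undefined")
})

test_that("ADC and FA are rotation invariant", {
  set.seed(17)
  p <- acquisition_protocol()
  D0 <- tensor_from_md_fa(15.04e-4, 0.45)
  m0 <- tensor_metrics(eigen(D0, symmetric = TRUE)$values)
  for (i in 1:5) {
    R <- random_rotation()
    # rotate tensor AND gradient set: metrics must not move
    p_rot <- p; p_rot$gradient_dirs <- p$gradient_dirs %*% t(R)
    tt <- tissue_truth(1000, 100, 0.3, R %*% D0 %*% t(R))
    fit <- fit_diffusion_tensor(simulate_dwi_series(tt, p_rot), p_rot)
    m <- tensor_metrics(fit$eigenvalues)
    expect_lt(abs(m$adc - m0$adc), 1e-9)
    expect_lt(abs(m$fa - m0$fa), 1e-9)
  }
})

test_that("FA increases with axial ratio at fixed ADC", {
  fas <- vapply(c(0.1, 0.3, 0.5, 0.7), function(fa) {
    ev <- eigen(tensor_from_md_fa(1e-3, fa), symmetric = TRUE)$values
    tensor_metrics(ev)$fa
  }, numeric(1))
  expect_true(all(diff(fas) > 0))
})

test_that("voxelwise maps equal direct fits and aggregate correctly", {
  truths <- list(NP = np_truth(), AF = af_truth())
  ph <- simulate_phantom(c(2, 2), truths)
  maps <- fit_voxelwise(ph$voxels, ph$protocol)
  agg <- roi_aggregate(maps)
  np <- agg[agg$roi == "NP", ]
  expect_equal(np$t1_mean, 1140, tolerance = 1e-4)
  expect_equal(np$t2_mean, 124, tolerance = 1e-9)
  expect_equal(np$mtr_mean, 0.34, tolerance = 1e-12)
  expect_equal(np$adc_mean, 15.04e-4, tolerance = 1e-9)
  expect_equal(np$fa_mean, 0.0803, tolerance = 1e-7)
  expect_equal(np$t1_sd, 0, tolerance = 1e-6)
  expect_equal(np$excluded_fraction, 0)
})

test_that("ROI aggregation excludes non-converged voxels with a reported fraction", {
  maps <- data.frame(voxel_id = 1:4, roi = "NP",
                     t1 = c(1000, 1100, 1200, 9999),
                     t2 = 100, mtr = 0.3, adc = 1e-3, fa = 0.1,
                     converged = c(TRUE, TRUE, TRUE, FALSE))
  agg <- roi_aggregate(maps)
  expect_equal(agg$t1_mean, 1100)
  expect_equal(agg$excluded_fraction, 0.25)
  maps$converged <- FALSE
  expect_error(roi_aggregate(maps), "empty after exclusion")
})
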