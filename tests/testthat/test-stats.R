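# ANOVA, post-hoc, regression, power and VIF.

test_that("one-way ANOVA matches hand-computed sums of squares", {
  vals <- c(1, 2, 3, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  grp <- rep(c("a", "b", "c", "d"), each = 3)
  gm <- tapply(vals, grp, mean); n <- 3
  ssb <- n * sum((gm - mean(vals))^2)
  ssw <- sum((vals - gm[grp])^2)
  f_hand <- (ssb / 3) / (ssw / 8)
  a <- one_way_anova(vals, grp)
  expect_equal(a$f, f_hand, tolerance = 1e-12)
  expect_equal(a$p, 1 - pf(f_hand, 3, 8), tolerance = 1e-12)
})

test_that("ANOVA limits: identical groups and fully separated groups", {
  a <- one_way_anova(rep(5, 12), rep(letters[1:4], each = 3))
  expect_equal(c(a$f, a$p), c(0, 1))
  set.seed(4)
  b <- suppressWarnings(
    one_way_anova(c(rnorm(3, 0, 1e-4), rnorm(3, 10, 1e-4),
                    rnorm(3, 20, 1e-4), rnorm(3, 30, 1e-4)),
                  rep(letters[1:4], each = 3)))
  expect_lt(b$p, 1e-6)
})

test_that("ANOVA F is invariant to shifts and scalings", {
  set.seed(8)
  vals <- rnorm(20); grp <- rep(letters[1:4], each = 5)
  f0 <- one_way_anova(vals, grp)$f
  expect_equal(one_way_anova(vals + 100, grp)$f, f0, tolerance = 1e-9)
  expect_equal(one_way_anova(vals * 7, grp)$f, f0, tolerance = 1e-9)
})

test_that("Dunn-Sidak adjustment applies the closed form and reduces to the raw test at m = 1", {
  set.seed(9)
  vals <- c(rnorm(5), rnorm(5, 2), rnorm(5, 4), rnorm(5, 1))
  grp <- rep(letters[1:4], each = 5)
  ds <- dunn_sidak_pairwise(vals, grp)
  expect_equal(nrow(ds), 6)
  expect_equal(ds$p_adjusted, 1 - (1 - ds$p_raw)^6, tolerance = 1e-12)
  expect_equal(1 - (1 - 0.01)^6, 0.05851985, tolerance = 1e-7)
  # two groups: adjusted equals raw equals the pooled-variance t test
  two <- dunn_sidak_pairwise(vals[1:10], grp[1:10])
  expect_equal(two$p_adjusted, two$p_raw)
  tt <- t.test(vals[1:5], vals[6:10], var.equal = TRUE)
  expect_equal(two$p_raw, tt$p.value, tolerance = 1e-12)
  expect_equal(dunn_sidak_pairwise(vals, grp)$p_adjusted[ds$p_raw == 0],
               numeric(0))  # no zero raw p here; formula maps 0 -> 0
  expect_equal(1 - (1 - 0)^6, 0)
})

test_that("multilinear fit equals the normal-equations oracle on a random fixture", {
  set.seed(21)
  X <- matrix(rnorm(15 * 5), 15, 5,
              dimnames = list(NULL, c("T1", "T2", "MTR", "ADC", "FA")))
  y <- rnorm(15)
  d <- data.frame(X, E = y)
  r <- fit_multilinear(d, "E")
  beta <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_equal(unname(r$coefficients), as.vector(beta), tolerance = 1e-10)
  sse <- sum((y - cbind(1, X) %*% beta)^2)
  expect_equal(r$r2, 1 - sse / sum((y - mean(y))^2), tolerance = 1e-12)
  expect_equal(r$see, sqrt(sse / (15 - 6)), tolerance = 1e-12)
})

test_that("R2 is near zero for an unrelated response and invariant to predictor rescaling", {
  set.seed(22)
  X <- matrix(rnorm(500 * 5), 500, 5,
              dimnames = list(NULL, c("T1", "T2", "MTR", "ADC", "FA")))
  d <- data.frame(X, E = rnorm(500))
  expect_lt(fit_multilinear(d, "E")$r2, 0.05)
  d2 <- d; d2$T1 <- d2$T1 * 1000 + 50
  expect_equal(fit_multilinear(d2, "E")$r2, fit_multilinear(d, "E")$r2,
               tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected", {
  set.seed(23)
  X <- matrix(rnorm(15 * 4), 15, 4)
  d <- data.frame(T1 = X[, 1], T2 = X[, 1], MTR = X[, 2], ADC = X[, 3],
                  FA = X[, 4], E = rnorm(15))
  expect_error(fit_multilinear(d, "E"), "rank-deficient")
})

test_that("regression power matches its limits and a Monte-Carlo oracle", {
  expect_equal(regression_power(0, 15, 5), 0.05, tolerance = 1e-12)
  expect_gt(regression_power(0.95, 15, 5), 0.99)
  expect_warning(p1 <- regression_power(1, 15, 5), "convention")
  expect_equal(p1, 1)
  # Monte-Carlo: sample the noncentral F by its chi-square construction
  r2 <- 0.70; n <- 15; p <- 5
  lam <- n * r2 / (1 - r2)
  set.seed(31)
  nmc <- 1e5
  fdraw <- (rchisq(nmc, p, ncp = lam) / p) / (rchisq(nmc, n - p - 1) / (n - p - 1))
  mc <- mean(fdraw > qf(0.95, p, n - p - 1))
  expect_lt(abs(regression_power(r2, n, p) - mc), 0.01)
  # the alternative convention uses the residual df multiplier
  expect_equal(regression_power(0.5, 20, 5, ncp_convention = "residual"),
               {lam2 <- 14 * 0.5 / 0.5
        1 - pf(qf(0.95, 5, 14), 5, 14, ncp = lam2)}, tolerance = 1e-12)
})

test_that("VIF matches the two-predictor closed form and flags collinearity", {
  n <- 40
  u <- rnorm(n); v <- rnorm(n)
  u <- scale(u)[, 1]
  v <- scale(residuals(lm(v ~ u)))[, 1]
  x2 <- 0.9 * u + sqrt(1 - 0.81) * v          # sample correlation exactly 0.9
  vif <- compute_vif(cbind(a = u, b = x2))
  expect_equal(unname(vif), rep(1 / (1 - 0.81), 2), tolerance = 1e-9)
  orth <- compute_vif(cbind(a = u, b = v))
  expect_equal(unname(orth), c(1, 1), tolerance = 1e-9)
  expect_warning(dup <- compute_vif(cbind(a = u, b = u)), "collinearity")
  expect_true(all(is.infinite(dup)))
})

test_that("VIF elimination removes the near-duplicate predictor with negligible R2 change", {
  set.seed(33)
  n <- 60
  T1 <- rnorm(n); MTR <- rnorm(n); ADC <- rnorm(n); FA <- rnorm(n)
  T2 <- T1 + rnorm(n, 0, 0.01)
  d <- data.frame(T1, T2, MTR, ADC, FA,
                  E = 2 * T1 + MTR - ADC + 0.5 * FA + rnorm(n, 0, 0.1))
  el <- vif_eliminate(d, "E", threshold = 10)
  expect_equal(el$trace$removed[2] %in% c("T1", "T2"), TRUE)
  expect_lt(abs(el$trace$delta_r2[2]), 0.01)
  expect_lt(max(el$result$vif), 10)
  # below-threshold and infinite-threshold cases are identities
  d2 <- data.frame(T1 = rnorm(n), T2 = rnorm(n), MTR = rnorm(n),
                   ADC = rnorm(n), FA = rnorm(n), E = rnorm(n))
  el2 <- vif_eliminate(d2, "E", threshold = 10)
  expect_equal(nrow(el2$trace), 1L)
  el3 <- vif_eliminate(d, "E", threshold = Inf)
  expect_equal(nrow(el3$trace), 1L)
  expect_setequal(el3$result$predictors, c("T1", "T2", "MTR", "ADC", "FA"))
})
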