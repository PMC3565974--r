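# Shared fixtures. Ground truths use the healthy nucleus pulposus group
# means; small geometries and short protocols keep tests fast.

np_truth <- function(s0 = 1000) {
  tissue_truth(t1 = 1140, t2 = 124, mtr = 0.34,
               tensor = tensor_from_md_fa(15.04e-4, 0.0803), s0 = s0)
}

af_truth <- function(s0 = 900) {
  tissue_truth(t1 = 706, t2 = 70, mtr = 0.44,
               tensor = tensor_from_md_fa(15.89e-4, 0.1583), s0 = s0)
}

disc_geometry <- function() specimen_geometry(radius = 2.5, thickness = 1.6)

# random rotation matrix via QR of a Gaussian matrix (deterministic under seed)
random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# brute-force T1 oracle: dense 2-D grid over (T1, S0), refined once
t1_grid_oracle <- function(series, protocol) {
  rss <- function(t1, s0)
    sum((series$y - ir_signal(series$x, t1, s0, protocol))^2)
  t1s <- seq(200, 3000, by = 5)
  s0s <- seq(0.5, 1.5, by = 0.01) * max(abs(series$y))
  best <- c(NA, NA, Inf)
  for (t1 in t1s) for (s0 in s0s) {
    v <- rss(t1, s0)
    if (v < best[3]) best <- c(t1, s0, v)
  }
  # one refinement pass around the grid optimum
  t1s <- seq(best[1] - 5, best[1] + 5, by = 0.1)
  s0s <- seq(best[2] * 0.99, best[2] * 1.01, length.out = 41)
  for (t1 in t1s) for (s0 in s0s) {
    v <- rss(t1, s0)
    if (v < best[3]) best <- c(t1, s0, v)
  }
  list(t1 = best[1], s0 = best[2])
}
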