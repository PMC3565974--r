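# Estimators for the five imaging biomarkers. Each fitter inverts the same
# forward model its generator evaluates (signal-models.R).

#' Fit T1 from an inversion-recovery series
#'
#' Variable-projection nonlinear least squares of the IR-TSE model: for each
#' candidate T1 the model is linear in S0, so S0 is solved in closed form and
#' T1 is found by a coarse log-spaced grid over \[10, 5000\] ms followed by
#' local refinement ([stats::optimize()]). For magnitude data
#' (`magnitude = TRUE`) polarity is restored by trying both signs for points
#' below the fitted null crossing.
#'
#' @param series `signal_series` of kind `"IR"` (>= 3 points).
#' @param protocol Protocol; defaults to the one stored in `series`.
#' @param magnitude Treat intensities as magnitude-reconstructed.
#' @param grid_n Number of coarse grid points.
#' @return List with `t1` (ms), `s0`, `diagnostics` (list: `rss`,
#'   `converged`, `degenerate`).
#' @examples
#' tt <- tissue_truth(1140, 124, 0.34, tensor_from_md_fa(15e-4, 0.08))
#' fit_t1(simulate_ir_series(tt))$t1
#' @export
fit_t1 <- function(series, protocol = series$protocol, magnitude = FALSE,
                   grid_n = 120L) {
  if (series$kind != "IR") stop("series must be of kind 'IR'")
  ti <- series$x; y <- series$y
  if (length(ti) < 3) stop("need at least 3 points to fit T1")
  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    return(list(t1 = NA_real_, s0 = mean(y),
                diagnostics = list(rss = 0, converged = FALSE, degenerate = TRUE)))
  }
  rss_of <- function(t1) {
    g <- ir_signal(ti, t1, 1, protocol)
    if (magnitude) {
      # polarity restoration: points before the model's zero crossing may be
      # flipped; choose per-point sign minimising the residual
      s0 <- sum(abs(y) * abs(g)) / sum(g^2)
      r2 <- pmin((abs(y) - s0 * g)^2, (-abs(y) - s0 * g)^2)
      return(list(rss = sum(r2), s0 = s0))
    }
    s0 <- sum(y * g) / sum(g^2)
    list(rss = sum((y - s0 * g)^2), s0 = s0)
  }
  grid <- exp(seq(log(10), log(5000), length.out = grid_n))
  rss <- vapply(grid, function(t) rss_of(t)$rss, numeric(1))
  i <- which.min(rss)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(grid_n, i + 1L)]
  opt <- stats::optimize(function(t) rss_of(t)$rss, c(lo, hi), tol = 1e-8)
  best <- rss_of(opt$minimum)
  list(t1 = opt$minimum, s0 = best$s0,
       diagnostics = list(rss = best$rss,
                          converged = is.finite(opt$minimum) && best$s0 > 0,
                          degenerate = FALSE))
}

#' Fit T2 from a multi-echo series (log-linear)
#'
#' Ordinary least squares of `ln SI` on TE; `T2 = -1/slope`,
#' `SI0 = exp(intercept)`. Exact on noiseless mono-exponential data.
#' Non-positive intensities are excluded with a warning.
#'
#' @param series `signal_series` of kind `"ECHO"`.
#' @return List with `t2` (ms), `si0`, `diagnostics` (`rss`, `converged`,
#'   `n_excluded`, `nondecaying`).
#' @export
fit_t2 <- function(series) {
  if (series$kind != "ECHO") stop("series must be of kind 'ECHO'")
  te <- series$x; y <- series$y
  keep <- y > 0
  if (any(!keep)) {
    warning(sprintf("excluding %d non-positive intensities from the T2 fit",
                    sum(!keep)))
    te <- te[keep]; y <- y[keep]
  }
  if (length(y) < 2) stop("fewer than 2 positive intensities; cannot fit T2")
  fit <- stats::lm.fit(cbind(1, te), log(y))
  slope <- fit$coefficients[[2]]
  nondecaying <- !is.finite(slope) || slope >= 0
  list(t2 = if (nondecaying) NA_real_ else -1 / slope,
       si0 = exp(fit$coefficients[[1]]),
       diagnostics = list(rss = sum(fit$residuals^2),
                          converged = !nondecaying,
                          n_excluded = sum(!keep),
                          nondecaying = nondecaying))
}

#' Magnetization transfer ratio
#'
#' `MTR = (M0 - MS) / M0` from the unsaturated/saturated pair.
#'
#' @param m0 Intensity without the off-resonance pulse, > 0.
#' @param ms Intensity with the pulse.
#' @return MTR as a fraction.
#' @export
compute_mtr <- function(m0, ms) {
  if (any(m0 <= 0)) stop("m0 must be > 0")
  (m0 - ms) / m0
}

#' Fit the diffusion tensor (log-linear least squares)
#'
#' For every direction g, `ln(SI/SI0) = -b g' D g`; the six unique tensor
#' entries solve the ordinary least-squares system with design rows
#' `b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)`.
#'
#' @param series `signal_series` of kind `"DWI"` (index 0 = b = 0 sample).
#' @param protocol Protocol; defaults to the one stored in `series`.
#' @return List with `tensor` (3 x 3), `eigenvalues` (descending),
#'   `eigenvectors`, `s0_fit`, `diagnostics`.
#' @export
fit_diffusion_tensor <- function(series, protocol = series$protocol) {
  if (series$kind != "DWI") stop("series must be of kind 'DWI'")
  g <- protocol$gradient_dirs; b <- protocol$b_value
  y0 <- series$y[series$x == 0]
  yd <- series$y[series$x != 0]
  if (length(y0) != 1 || length(yd) != nrow(g))
    stop("series does not match the protocol's direction set")
  keep <- yd > 0 & y0 > 0
  if (any(!keep)) {
    warning(sprintf("excluding %d non-positive diffusion signals", sum(!keep)))
  }
  if (sum(keep) < 6) stop("fewer than 6 usable directions: underdetermined")
  gk <- g[keep, , drop = FALSE]
  X <- b * cbind(gk[, 1]^2, gk[, 2]^2, gk[, 3]^2,
                 2 * gk[, 1] * gk[, 2], 2 * gk[, 1] * gk[, 3],
                 2 * gk[, 2] * gk[, 3])
  if (qr(X)$rank < 6) stop("rank-deficient diffusion design")
  rhs <- -log(yd[keep] / y0)
  fit <- stats::lm.fit(X, rhs)
  d <- fit$coefficients
  D <- matrix(c(d[1], d[4], d[5],
                d[4], d[2], d[6],
                d[5], d[6], d[3]), 3, 3)
  ed <- eigen(D, symmetric = TRUE)
  list(tensor = D, eigenvalues = ed$values, eigenvectors = ed$vectors,
       s0_fit = y0,
       diagnostics = list(rss = sum(fit$residuals^2),
                          n_excluded = sum(!keep), converged = TRUE))
}

#' Scalar tensor metrics: ADC (mean diffusivity) and FA
#'
#' `ADC = (l1 + l2 + l3)/3`;
#' `FA = sqrt(3 * sum((l - ADC)^2)) / sqrt(2 * sum(l^2))`, clipped to
#' \[0, 1\] (clipping is reported, not silent).
#'
#' @param eigenvalues Numeric length-3 vector, or the list returned by
#'   [fit_diffusion_tensor()].
#' @return List with `adc`, `fa`, `fa_clipped` (logical).
#' @examples
#' tensor_metrics(c(3, 2, 1))  # adc 2, fa sqrt(6/28)
#' @export
tensor_metrics <- function(eigenvalues) {
  if (is.list(eigenvalues)) eigenvalues <- eigenvalues$eigenvalues
  l <- as.numeric(eigenvalues)
  if (length(l) != 3 || any(!is.finite(l))) stop("need 3 finite eigenvalues")
  if (all(l == 0)) stop("all-zero eigenvalues: FA undefined")
  adc <- mean(l)
  fa_raw <- sqrt(3 * sum((l - adc)^2)) / sqrt(2 * sum(l^2))
  fa <- min(max(fa_raw, 0), 1)
  list(adc = adc, fa = fa, fa_clipped = fa_raw > 1 || fa_raw < 0)
}

#' Voxelwise parameter maps from a phantom voxel table
#'
#' Applies the four fitters to every non-background voxel of a
#' [simulate_phantom()] voxel table (or any long table with the same
#' columns). Background voxels are skipped.
#'
#' @param voxels Long data.frame with columns voxel_id, roi, sequence,
#'   index_value, signal.
#' @param protocol The acquisition protocol the signals were generated under.
#' @param magnitude_ir Passed to [fit_t1()].
#' @return data.frame, one row per voxel: voxel_id, roi, t1, t2, mtr, adc,
#'   fa, converged.
#' @export
fit_voxelwise <- function(voxels, protocol = acquisition_protocol(),
                          magnitude_ir = FALSE) {
  need <- c("voxel_id", "roi", "sequence", "index_value", "signal")
  if (!all(need %in% names(voxels))) stop("voxel table lacks required columns")
  voxels <- voxels[voxels$roi != "background", , drop = FALSE]
  ids <- unique(voxels$voxel_id)
  out <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    v <- voxels[voxels$voxel_id == ids[j], ]
    ir <- v[v$sequence == "IR", ]; ec <- v[v$sequence == "ECHO", ]
    mt <- v[v$sequence == "MT", ]; dw <- v[v$sequence == "DWI", ]
    f1 <- fit_t1(new_signal_series("IR", ir$index_value, ir$signal, protocol),
                 protocol, magnitude = magnitude_ir)
    f2 <- fit_t2(new_signal_series("ECHO", ec$index_value, ec$signal, protocol))
    mtr <- compute_mtr(mt$signal[mt$index_value == 0],
                       mt$signal[mt$index_value == 1])
    fd <- fit_diffusion_tensor(
      new_signal_series("DWI", dw$index_value, dw$signal, protocol), protocol)
    tm <- tensor_metrics(fd$eigenvalues)
    out[[j]] <- data.frame(
      voxel_id = ids[j], roi = v$roi[1],
      t1 = f1$t1, t2 = f2$t2, mtr = mtr, adc = tm$adc, fa = tm$fa,
      converged = isTRUE(f1$diagnostics$converged) &&
        isTRUE(f2$diagnostics$converged) && isTRUE(fd$diagnostics$converged)
    )
  }
  do.call(rbind, out)
}

#' Aggregate voxelwise maps over regions of interest
#'
#' Per-ROI mean and SD of each parameter over converged voxels only; the
#' excluded fraction is reported.
#'
#' @param maps Output of [fit_voxelwise()].
#' @return data.frame with one row per ROI: roi, n, excluded_fraction and
#'   `<param>_mean` / `<param>_sd` for t1, t2, mtr, adc, fa.
#' @export
roi_aggregate <- function(maps) {
  params <- c("t1", "t2", "mtr", "adc", "fa")
  rois <- unique(maps$roi)
  out <- vector("list", length(rois))
  for (j in seq_along(rois)) {
    m <- maps[maps$roi == rois[j], ]
    ok <- m[m$converged, , drop = FALSE]
    if (nrow(ok) == 0) stop(sprintf("ROI '%s' empty after exclusion", rois[j]))
    row <- list(roi = rois[j], n = nrow(ok),
                excluded_fraction = 1 - nrow(ok) / nrow(m))
    for (p in params) {
      row[[paste0(p, "_mean")]] <- mean(ok[[p]])
      row[[paste0(p, "_sd")]] <- if (nrow(ok) > 1) stats::sd(ok[[p]]) else 0
    }
    out[[j]] <- as.data.frame(row)
  }
  do.call(rbind, out)
}
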