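# Generators for the four quantitative MRI sequences. Each emits a
# `signal_series` whose forward model is shared verbatim with the fitters.

new_signal_series <- function(kind, x, y, protocol) {
  kind <- match.arg(kind, c("IR", "ECHO", "MT", "DWI"))
  if (length(x) != length(y) && kind != "DWI")
    stop("x and y must have equal length")
  if (any(!is.finite(y))) stop("signal intensities must be finite")
  structure(list(kind = kind, x = x, y = as.numeric(y), protocol = protocol),
            class = "signal_series")
}

#' Simulate an inversion-recovery series
#'
#' Evaluates the shared IR-TSE forward model ([ir_signal()]) at the
#' protocol's inversion times. Signed (real) values by default; set
#' `magnitude = TRUE` for magnitude-reconstructed data.
#'
#' @param truth A [tissue_truth()].
#' @param protocol An [acquisition_protocol()].
#' @param magnitude Apply `abs()` to emulate magnitude reconstruction.
#' @return A `signal_series` of kind `"IR"` (x = TI in ms).
#' @export
simulate_ir_series <- function(truth, protocol = acquisition_protocol(),
                               magnitude = FALSE) {
  ti <- protocol$inversion_times
  if (length(ti) < 3) stop("need at least 3 inversion times")
  y <- ir_signal(ti, truth$t1, truth$s0, protocol)
  if (magnitude) y <- abs(y)
  new_signal_series("IR", ti, y, protocol)
}

#' Simulate a multi-echo T2 decay series
#'
#' @inheritParams simulate_ir_series
#' @return A `signal_series` of kind `"ECHO"` (x = TE in ms).
#' @export
simulate_echo_series <- function(truth, protocol = acquisition_protocol()) {
  te <- protocol$echo_times_t2
  if (length(te) < 2) stop("need at least 2 echo times")
  new_signal_series("ECHO", te, echo_signal(te, truth$t2, truth$s0), protocol)
}

#' Simulate a magnetization-transfer image pair
#'
#' Returns the intensities without (`m0`) and with (`ms`) the off-resonance
#' saturation pulse: `ms = m0 * (1 - mtr)`.
#'
#' @param truth A [tissue_truth()]; `truth$mtr` is the ground-truth ratio.
#' @param m0 Unsaturated intensity, > 0.
#' @return Named numeric vector `c(m0, ms)`.
#' @export
simulate_mt_pair <- function(truth, m0 = truth$s0) {
  stopifnot_scalar(m0, "m0", positive = TRUE)
  if (truth$mtr < 0 || truth$mtr > 1) stop("mtr must lie in [0, 1]")
  c(m0 = m0, ms = m0 * (1 - truth$mtr))
}

#' Simulate a diffusion-weighted series
#'
#' One b = 0 sample followed by one diffusion-weighted sample per gradient
#' direction, each `SI = SI0 * exp(-b g' D g)`.
#'
#' @inheritParams simulate_ir_series
#' @return A `signal_series` of kind `"DWI"`; `x` is the direction index
#'   with 0 denoting the b = 0 sample.
#' @export
simulate_dwi_series <- function(truth, protocol = acquisition_protocol()) {
  g <- protocol$gradient_dirs
  if (nrow(g) < 6) stop("need at least 6 diffusion directions")
  if (qr(g)$rank < 3)
    warning("gradient directions span rank < 3; tensor will be unidentifiable")
  y <- c(truth$s0, dwi_signal(g, truth$tensor, protocol$b_value, truth$s0))
  new_signal_series("DWI", 0:nrow(g), y, protocol)
}

#' Add Rician noise to a signal series or numeric vector
#'
#' Each value v is replaced by `sqrt((v + n1)^2 + n2^2)` with n1, n2
#' independent Gaussian(0, sigma): the magnitude-MRI noise model. With
#' `sigma = 0` the input is returned unchanged.
#'
#' @param series A `signal_series` or numeric vector.
#' @param sigma Noise standard deviation in signal units, >= 0.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return Same type as `series`.
#' @examples
#' add_rician_noise(c(0, 100), sigma = 1, seed = 1)
#' @export
add_rician_noise <- function(series, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  noisy <- function(v) {
    if (sigma == 0) return(v)
    with_seed(seed, {
      n1 <- stats::rnorm(length(v), 0, sigma)
      n2 <- stats::rnorm(length(v), 0, sigma)
      sqrt((v + n1)^2 + n2^2)
    })
  }
  if (inherits(series, "signal_series")) {
    series$y <- noisy(series$y)
    series
  } else noisy(series)
}

#' Simulate a segmented multi-sequence phantom
#'
#' Builds a rectangular voxel grid whose voxels carry a nucleus-pulposus
#' (NP), annulus-fibrosus (AF) or background label, generates all four
#' sequence series per labelled voxel from the per-region ground truths, and
#' optionally corrupts the stacks with Rician noise. Stands in for a
#' segmented disc acquisition.
#'
#' @param shape Integer vector (nx, ny) of the voxel grid.
#' @param truths Named list with elements `NP` and `AF`, each a
#'   [tissue_truth()].
#' @param labels Character matrix of `shape` with entries
#'   `"NP"`, `"AF"` or `"background"`. Default: left half NP, right half AF.
#' @param noise_sigma Rician sigma in signal units (0 = noiseless).
#' @param seed Integer seed for the noise draws.
#' @param protocol An [acquisition_protocol()].
#' @return A `disc_phantom`: list with `voxels` (long data.frame with columns
#'   voxel_id, roi, sequence, index_value, signal), `labels`, `truths`,
#'   `protocol`, `noise_sigma`, `seed`.
#' @export
simulate_phantom <- function(shape = c(4L, 4L), truths,
                             labels = NULL, noise_sigma = 0, seed = 1L,
                             protocol = acquisition_protocol()) {
  if (prod(shape) < 1) stop("empty grid")
  if (is.null(labels)) {
    labels <- matrix("AF", shape[1], shape[2])
    labels[, seq_len(max(1L, floor(shape[2] / 2)))] <- "NP"
  }
  if (!all(dim(labels) == shape)) stop("labels shape must match grid shape")
  if (!any(labels == "NP") || !any(labels == "AF"))
    stop("need at least one NP and one AF voxel")
  rois <- as.vector(labels)
  idx <- which(rois != "background")
  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    v <- idx[j]
    tt <- truths[[rois[v]]]
    ir <- simulate_ir_series(tt, protocol)
    ec <- simulate_echo_series(tt, protocol)
    mt <- simulate_mt_pair(tt)
    dw <- simulate_dwi_series(tt, protocol)
    rows[[j]] <- data.frame(
      voxel_id = v,
      roi = rois[v],
      sequence = c(rep("IR", length(ir$y)), rep("ECHO", length(ec$y)),
                   rep("MT", 2L), rep("DWI", length(dw$y))),
      index_value = c(ir$x, ec$x, 0:1, dw$x),
      signal = c(ir$y, ec$y, unname(mt), dw$y)
    )
  }
  voxels <- do.call(rbind, rows)
  if (noise_sigma > 0) {
    voxels$signal <- add_rician_noise(voxels$signal, noise_sigma, seed = seed)
  }
  structure(list(voxels = voxels, labels = labels, truths = truths,
                 protocol = protocol, noise_sigma = noise_sigma, seed = seed),
            class = "disc_phantom")
}
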