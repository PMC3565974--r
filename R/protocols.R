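#' MRI acquisition protocol
#'
#' Bundles the timing and diffusion-encoding parameters of the four
#' quantitative sequences: an inversion-recovery turbo-spin-echo (T1), a
#' multi-echo TSE (T2), a magnetization-transfer pair (MTR) and a
#' diffusion-weighted acquisition (ADC/FA). Defaults reproduce a 3 T disc
#' protocol: 15 inversion times from 50 to 1900 ms with TR/TE = 2100/6.3 ms
#' and an 8-pulse refocusing train; 10 echoes every 15 ms; b = 1000 s/mm^2
#' with 15 non-collinear directions.
#'
#' @param inversion_times Inversion times TI (ms), strictly increasing.
#' @param echo_times_t2 Echo times TE (ms), strictly increasing.
#' @param tr Repetition time of the IR sequence (ms).
#' @param te_readout Echo spacing of the IR readout train (ms).
#' @param n_refocus Number of refocusing pulses N (>= 1).
#' @param flip_alpha Refocusing flip angle alpha (degrees).
#' @param mt_offset Off-resonance MT pulse frequency (Hz, metadata only).
#' @param b_value Diffusion weighting b (s/mm^2).
#' @param gradient_dirs Matrix (n x 3) of unit diffusion directions.
#'
#' @return An object of class `acquisition_protocol`.
#' @examples
#' p <- acquisition_protocol()
#' length(p$inversion_times)  # 15
#' @export
acquisition_protocol <- function(inversion_times = seq(50, 1900, length.out = 15),
                                 echo_times_t2 = seq(15, 150, by = 15),
                                 tr = 2100,
                                 te_readout = 6.3,
                                 n_refocus = 8L,
                                 flip_alpha = 180,
                                 mt_offset = 1100,
                                 b_value = 1000,
                                 gradient_dirs = gradient_scheme(15L)) {
  if (any(inversion_times <= 0) || is.unsorted(inversion_times, strictly = TRUE))
    stop("inversion times must be positive and strictly increasing")
  if (any(echo_times_t2 <= 0) || is.unsorted(echo_times_t2, strictly = TRUE))
    stop("echo times must be positive and strictly increasing")
  if (n_refocus < 1) stop("n_refocus must be >= 1")
  if (b_value < 0) stop("b_value must be >= 0")
  gradient_dirs <- as.matrix(gradient_dirs)
  if (ncol(gradient_dirs) != 3L) stop("gradient_dirs must be n x 3")
  nrm <- sqrt(rowSums(gradient_dirs^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("gradient directions must have unit norm")
  structure(list(
    inversion_times = as.numeric(inversion_times),
    echo_times_t2 = as.numeric(echo_times_t2),
    tr = tr, te_readout = te_readout, n_refocus = as.integer(n_refocus),
    flip_alpha = flip_alpha, mt_offset = mt_offset, b_value = b_value,
    gradient_dirs = gradient_dirs
  ), class = "acquisition_protocol")
}

#' Deterministic near-uniform diffusion gradient scheme
#'
#' Fibonacci-hemisphere construction: a fixed formula, so the scheme is
#' identical across runs and platforms. Directions are well spread and of
#' full rank for any `n >= 6`.
#'
#' @param n Number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
gradient_scheme <- function(n = 15L) {
  if (n < 6) stop("need at least 6 directions for tensor estimation")
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i       # golden-angle azimuth
  z <- i / n                          # hemisphere: z in (0, 1)
  s <- sqrt(1 - z^2)
  g <- cbind(s * cos(phi), s * sin(phi), z)
  g / sqrt(rowSums(g^2))
}

#' Tissue ground truth for the MRI generators
#'
#' @param t1,t2 Relaxation times (ms), `t1 > t2 > 0`.
#' @param mtr Magnetization transfer ratio, a fraction in \[0, 1\].
#' @param tensor Symmetric positive semi-definite 3 x 3 diffusion tensor
#'   (mm^2/s), e.g. from [tensor_from_md_fa()].
#' @param s0 Proton-density signal scale (> 0).
#' @return An object of class `tissue_truth`.
#' @examples
#' tt <- tissue_truth(t1 = 1140, t2 = 124, mtr = 0.34,
#'                    tensor = tensor_from_md_fa(15.04e-4, 0.0803))
#' @export
tissue_truth <- function(t1, t2, mtr, tensor, s0 = 1000) {
  stopifnot_scalar(t1, "t1", positive = TRUE)
  stopifnot_scalar(t2, "t2", positive = TRUE)
  if (t1 <= t2) stop("t1 must exceed t2")
  if (mtr < 0 || mtr > 1) stop("mtr must lie in [0, 1]")
  stopifnot_scalar(s0, "s0", positive = TRUE)
  tensor <- as.matrix(tensor)
  if (any(dim(tensor) != c(3L, 3L)) || max(abs(tensor - t(tensor))) > 1e-12)
    stop("tensor must be a symmetric 3 x 3 matrix")
  if (min(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("tensor must be positive semi-definite")
  structure(list(t1 = t1, t2 = t2, mtr = mtr, tensor = tensor, s0 = s0),
            class = "tissue_truth")
}
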