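# Shared forward models for the four quantitative sequences. The generators
# and the fitters call these same functions: recovery tests are exact round
# trips of one model, not comparisons of two renditions of it.

#' Inversion-recovery TSE signal model
#'
#' Signed signal intensity of an IR turbo-spin-echo readout:
#' \deqn{SI(TI) = S_0 [1 - (1-\cos\alpha) E_{TI} (1 - E_{TW} f(N) (1 - E_{TE}/2)^2)]}
#' with \eqn{E_x = e^{-x/T_1}}, \eqn{f(N) = 1 - E_{TE}^N} and
#' \eqn{TW = TR - TI - N\,TE} (clamped at 0), the recovery interval between
#' the last refocusing pulse and the next inversion.
#'
#' @param ti Inversion times (ms).
#' @param t1 Longitudinal relaxation time (ms), > 0.
#' @param s0 Equilibrium signal.
#' @param protocol An [acquisition_protocol()] supplying TR, TE and N.
#' @return Numeric vector of signed signal intensities.
#' @export
ir_signal <- function(ti, t1, s0, protocol) {
  stopifnot_scalar(t1, "t1", positive = TRUE)
  tr <- protocol$tr; te <- protocol$te_readout; n <- protocol$n_refocus
  alpha <- protocol$flip_alpha * pi / 180
  tw <- pmax(tr - ti - n * te, 0)
  if (all(tr - ti - n * te < 0))
    warning("recovery interval TW clamped at 0 for every TI; protocol infeasible")
  e_ti <- exp(-ti / t1)
  e_tw <- exp(-tw / t1)
  e_te <- exp(-te / t1)
  f_n <- 1 - e_te^n
  s0 * (1 - (1 - cos(alpha)) * e_ti * (1 - e_tw * f_n * (1 - e_te / 2)^2))
}

#' Mono-exponential spin-echo decay
#'
#' \eqn{SI(TE) = SI(0)\,e^{-TE/T_2}}.
#'
#' @param te Echo times (ms).
#' @param t2 Transverse relaxation time (ms), > 0.
#' @param si0 Signal at TE = 0.
#' @return Numeric vector.
#' @export
echo_signal <- function(te, t2, si0) {
  stopifnot_scalar(t2, "t2", positive = TRUE)
  si0 * exp(-te / t2)
}

#' Diffusion-weighted signal for one direction
#'
#' \eqn{SI = SI_{b=0}\, e^{-b\, g^T D g}} for a unit direction g.
#'
#' @param g Unit direction vector (length 3) or n x 3 matrix.
#' @param tensor Symmetric 3 x 3 diffusion tensor (mm^2/s).
#' @param b b-value (s/mm^2).
#' @param si0 Non-diffusion-weighted signal.
#' @return Numeric vector, one value per direction.
#' @export
dwi_signal <- function(g, tensor, b, si0) {
  g <- if (is.null(dim(g))) matrix(g, ncol = 3) else as.matrix(g)
  q <- rowSums((g %*% tensor) * g)      # g' D g per row
  si0 * exp(-b * q)
}

#' Construct an axially symmetric tensor with prescribed MD and FA
#'
#' Returns a positive semi-definite tensor whose mean diffusivity and
#' fractional anisotropy are exactly the requested values:
#' \eqn{\lambda_\parallel = MD(1 + 2 FA/\sqrt{3 - 2 FA^2})},
#' \eqn{\lambda_\perp = MD(1 - FA/\sqrt{3 - 2 FA^2})}.
#'
#' @param md Mean diffusivity (mm^2/s), > 0.
#' @param fa Fractional anisotropy in \[0, 1).
#' @param axis Principal axis (unit 3-vector); normalised internally.
#' @return Symmetric 3 x 3 matrix.
#' @examples
#' D <- tensor_from_md_fa(15.04e-4, 0.0803)
#' tensor_metrics(eigen(D, symmetric = TRUE)$values)
#' @export
tensor_from_md_fa <- function(md, fa, axis = c(0, 0, 1)) {
  stopifnot_scalar(md, "md", positive = TRUE)
  if (fa < 0 || fa >= 1) stop("fa must lie in [0, 1)")
  s <- fa / sqrt(3 - 2 * fa^2)
  l_par <- md * (1 + 2 * s)
  l_perp <- md * (1 - s)
  if (l_perp <= 0) stop("fa too large: transverse eigenvalue would be <= 0")
  axis <- axis / sqrt(sum(axis^2))
  l_perp * diag(3) + (l_par - l_perp) * tcrossprod(axis)
}
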