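# Forward models for the three mechanical tests. Strain is handled
# compressive-negative internally; geometry is user-facing in mm, converted
# to SI here. Moduli are MPa user-facing (Pa internally), permeabilities are
# in reporting units of 1e-15 m^4/(N s) user-facing (SI internally).

MPA <- 1e6
KPERM <- 1e-15
MM <- 1e-3

#' Specimen geometry for compression and permeametry tests
#' @param radius Specimen radius (mm).
#' @param thickness Specimen thickness (mm).
#' @return list with radius/thickness (mm) and derived SI `radius_m`,
#'   `thickness_m`, `area_m2`.
#' @export
specimen_geometry <- function(radius = 2.5, thickness = 1.6) {
  stopifnot_scalar(radius, "radius", positive = TRUE)
  stopifnot_scalar(thickness, "thickness", positive = TRUE)
  list(radius = radius, thickness = thickness,
       radius_m = radius * MM, thickness_m = thickness * MM,
       area_m2 = pi * (radius * MM)^2)
}

# --- confined compression: linear closed form ------------------------------

# S(tau) = sum_{n>=1} n^-2 exp(-n^2 tau); small-tau branch uses the
# theta-function asymptotic pi^2/6 - sqrt(pi*tau) + tau/2 (error is
# O(exp(-pi^2/tau)), negligible for tau <= 0.05).
consolidation_sum <- function(tau) {
  vapply(tau, function(s) {
    if (s <= 0) return(pi^2 / 6)
    if (s < 0.05) return(pi^2 / 6 - sqrt(pi * s) + s / 2)
    n_max <- max(3L, ceiling(sqrt(30 / s)))
    n <- seq_len(n_max)
    sum(exp(-n^2 * s) / n^2)
  }, numeric(1))
}

#' Linear biphasic confined-compression stress (closed-form series)
#'
#' One-dimensional consolidation of a biphasic sample of thickness h between
#' an impermeable moving platen and a free-draining support. For a
#' displacement ramp at rate V the platen stress is
#' \deqn{\sigma(t) = H_{A0} V t/h + (V h/k)[1/3 - (2/\pi^2)\sum n^{-2}
#'   e^{-n^2\pi^2 H_{A0} k t / h^2}]}
#' and an arbitrary piecewise-linear displacement schedule is obtained by
#' superposition. Series truncation keeps terms until the relative change is
#' below 1e-10.
#'
#' @param h_a0 Aggregate modulus (MPa).
#' @param k_0 Axial permeability (units of 1e-15 m^4/(N s)).
#' @param geometry A [specimen_geometry()].
#' @param schedule data.frame with columns `t` (s) and `strain`
#'   (compressive strain magnitude), piecewise-linear breakpoints.
#' @param times Output times (s).
#' @return Numeric vector of compressive platen stress (MPa) at `times`.
#' @export
confined_forward_linear <- function(h_a0, k_0, geometry, schedule, times) {
  stopifnot_scalar(h_a0, "h_a0", positive = TRUE)
  stopifnot_scalar(k_0, "k_0", positive = TRUE)
  ha <- h_a0 * MPA; k <- k_0 * KPERM
  h <- geometry$thickness_m
  D <- ha * k
  # unit-rate infinite-ramp response (displacement rate 1 m/s), t >= 0
  ramp_resp <- function(t) {
    out <- numeric(length(t))
    pos <- t > 0
    tau <- pi^2 * D * t[pos] / h^2
    out[pos] <- ha * t[pos] / h +
      (h / k) * (1 / 3 - (2 / pi^2) * consolidation_sum(tau))
    out
  }
  sigma <- numeric(length(times))
  seg <- schedule_segments(schedule)
  for (i in seq_len(nrow(seg))) {
    v <- seg$rate[i] * h  # strain rate -> displacement rate (m/s)
    if (v == 0) next
    sigma <- sigma + v * (ramp_resp(times - seg$t0[i]) -
                            ramp_resp(times - seg$t1[i]))
  }
  sigma / MPA
}

# break a piecewise-linear strain schedule into constant-rate segments
schedule_segments <- function(schedule) {
  stopifnot(all(c("t", "strain") %in% names(schedule)))
  if (is.unsorted(schedule$t, strictly = TRUE))
    stop("schedule times must be strictly increasing")
  n <- nrow(schedule)
  data.frame(t0 = schedule$t[-n], t1 = schedule$t[-1],
             rate = diff(schedule$strain) / diff(schedule$t),
             eps0 = schedule$strain[-n])
}

# --- confined compression: nonlinear finite differences --------------------

#' Nonlinear biphasic confined-compression stress (finite differences)
#'
#' Method-of-lines solution of the 1-D nonlinear consolidation equation
#' \deqn{\partial\epsilon/\partial t = \partial_z [k(\epsilon) H_A(\epsilon)
#'   \partial_z \epsilon]}
#' with strain-dependent laws \eqn{H_A(\epsilon) = H_{A0} e^{\beta\epsilon}}
#' and \eqn{k(\epsilon) = k_0 e^{M\epsilon}} (strain compressive-negative),
#' an impermeable moving platen on top and a free-draining support at the
#' bottom. The finite-volume flux form conserves fluid mass exactly; time
#' integration uses [deSolve::ode()] (lsoda, banded Jacobian). The platen
#' stress is the constitutive stress at the drained face,
#' \eqn{\sigma = H_{A0}(e^{\beta\epsilon(0,t)} - 1)/\beta}.
#'
#' @inheritParams confined_forward_linear
#' @param beta Stiffening coefficient of the aggregate modulus (unitless).
#' @param m_perm Strain coefficient of the permeability (unitless).
#' @param n_nodes Spatial grid size (default 101).
#' @param y0 Optional initial strain field (internal, for chained solves).
#' @param full Return the strain field and times as attributes.
#' @param rtol,atol Integrator tolerances.
#' @return Compressive platen stress (MPa) at `times`; with `full = TRUE`,
#'   attributes `state` (final strain field) and `fields` (matrix of strain
#'   fields at `times`).
#' @export
confined_forward_nonlinear <- function(h_a0, k_0, beta, m_perm, geometry,
                                       schedule, times, n_nodes = 101L,
                                       y0 = NULL, full = FALSE,
                                       rtol = 1e-8, atol = 1e-10) {
  stopifnot_scalar(h_a0, "h_a0", positive = TRUE)
  stopifnot_scalar(k_0, "k_0", positive = TRUE)
  ha <- h_a0 * MPA; k0 <- k_0 * KPERM
  h <- geometry$thickness_m
  n <- as.integer(n_nodes)
  dz <- h / (n - 1)
  widths <- c(dz / 2, rep(dz, n - 2), dz / 2)
  if (is.null(y0)) y0 <- rep(0, n)

  seg <- schedule_segments(schedule)
  # piecewise-constant displacement rate (m/s), compressive-negative
  rate_at <- function(i_seg) -seg$rate[i_seg] * h

  rhs <- function(t, eps, parms) {
    kappa <- (k0 * exp(m_perm * eps)) * (ha * exp(beta * eps))  # k*HA per node
    km <- 0.5 * (kappa[-1] + kappa[-n])
    flux <- km * diff(eps) / dz              # interior face fluxes
    f_bottom <- -parms$udot                  # drained face: balances platen motion
    dd <- c(flux[1] - f_bottom, diff(flux), -flux[n - 1]) / widths
    list(dd)
  }

  all_t <- sort(unique(c(times, seg$t0, seg$t1)))
  fields <- matrix(NA_real_, length(all_t), n)
  state <- y0
  for (i in seq_len(nrow(seg))) {
    tt <- all_t[all_t >= seg$t0[i] & all_t <= seg$t1[i]]
    tt_run <- unique(c(seg$t0[i], tt, seg$t1[i]))
    sol <- deSolve::ode(y = state, times = tt_run, func = rhs,
                        parms = list(udot = rate_at(i)),
                        method = "lsoda", jactype = "bandint",
                        bandup = 1, banddown = 1, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf(paste0("confined solver failed in segment %d ",
                          "(t = %.1f..%.1f s, %d nodes): try a finer grid ",
                          "or looser tolerances"),
                   i, seg$t0[i], seg$t1[i], n))
    keep <- match(tt, sol[, 1])
    fields[match(tt, all_t), ] <- sol[keep, -1, drop = FALSE]
    state <- sol[nrow(sol), -1]
  }
  eps_bottom <- fields[match(times, all_t), 1]
  sigma <- if (abs(beta) < 1e-12) -ha * eps_bottom else
    -ha * (exp(beta * eps_bottom) - 1) / beta
  out <- sigma / MPA
  if (full) {
    attr(out, "state") <- state
    attr(out, "fields") <- fields[match(times, all_t), , drop = FALSE]
    attr(out, "widths") <- widths
  }
  out
}

# --- unconfined compression ------------------------------------------------

# Semi-discrete radial biphasic operator. State x = phi_i at cell centers,
# phi = (1/r) d(r u)/dr. Returns system matrices so the time response can be
# evaluated in closed form (the model is linear).
unconfined_system <- function(e_young, nu, k_r, geometry, n = 40L) {
  E <- e_young * MPA; k <- k_r * KPERM
  mu_s <- E / (2 * (1 + nu))
  lam_s <- E * nu / ((1 + nu) * (1 - 2 * nu))
  ha <- lam_s + 2 * mu_s
  a <- geometry$radius_m
  D <- ha * k
  dr <- a / n
  r <- (seq_len(n) - 0.5) * dr
  w <- r * dr / a^2                         # quadrature weights: sum(w) = 1/2
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    rp <- if (i < n) r[i] + dr / 2 else a
    rm <- r[i] - dr / 2
    if (i > 1) {
      A[i, i - 1] <- A[i, i - 1] + D * rm / (r[i] * dr^2)
      A[i, i] <- A[i, i] - D * rm / (r[i] * dr^2)
    }
    if (i < n) {
      A[i, i + 1] <- A[i, i + 1] + D * rp / (r[i] * dr^2)
      A[i, i] <- A[i, i] - D * rp / (r[i] * dr^2)
    }
  }
  # outer face: gradient to the boundary value phi_b over dr/2, where the
  # lateral-surface condition sigma_rr = 0, p = 0 gives
  # phi_b = (2 mu_s * w.x - lam_s * eps_z) / HA
  cb <- D * a / (r[n] * dr * (dr / 2))
  A[n, ] <- A[n, ] + cb * (2 * mu_s / ha) * w
  A[n, n] <- A[n, n] - cb
  g <- rep(0, n); g[n] <- -cb * lam_s / ha
  list(A = A, g = g, w = w, mu_s = mu_s, lam_s = lam_s, ha = ha,
       E = E, D = D, a = a, n = n)
}

# closed-form response of xdot = A x + g*eps(t) + h*epsdot for one ramp
# (strain 0 -> -d_eps over [0, dur], then hold), evaluated at times t >= 0.
# Output: w' x(t) and eps(t).
ramp_mode_response <- function(sys, d_eps, dur, t) {
  ed <- eigen(sys$A)
  Q <- ed$vectors; lam <- ed$values
  Qi <- solve(Q)
  hv <- rep(-1, sys$n)
  v <- -d_eps / dur                          # internal signed strain rate
  # segment 1: eps = v s, forcing u0 = h v, u1 = g v
  u0 <- hv * v; u1 <- sys$g * v
  p0 <- Q %*% ((Qi %*% u0) / lam)            # A^-1 u0
  p1 <- Q %*% ((Qi %*% u1) / lam)
  q1 <- -p1; q0 <- Q %*% ((Qi %*% (q1 - u0)) / lam)
  z0 <- Qi %*% (rep(0, sys$n) - q0)          # x0 = 0
  wQ <- as.vector(t(sys$w) %*% Q)
  wq0 <- sum(sys$w * q0); wq1 <- sum(sys$w * q1)
  eval_seg1 <- function(s) {
    em <- exp(outer(lam, s))                 # modes x times
    as.vector(crossprod(em, wQ * as.vector(z0))) + wq0 + wq1 * s
  }
  x_end_seg1 <- function(s) Re(Q %*% (as.vector(z0) * exp(lam * s)) + q0 + q1 * s)
  # segment 2 (hold): eps = -d_eps constant; forcing u0h = g * (-d_eps)
  u0h <- sys$g * (-d_eps)
  p0h <- Q %*% ((Qi %*% u0h) / lam)
  x1 <- x_end_seg1(dur)
  z0h <- Qi %*% (x1 + p0h)
  eval_seg2 <- function(s) {
    em <- exp(outer(lam, s))
    as.vector(crossprod(em, wQ * as.vector(z0h))) - sum(sys$w * p0h)
  }
  wx <- numeric(length(t)); eps <- numeric(length(t))
  s1 <- t >= 0 & t <= dur; s2 <- t > dur
  if (any(s1)) { wx[s1] <- Re(eval_seg1(t[s1])); eps[s1] <- v * t[s1] }
  if (any(s2)) { wx[s2] <- Re(eval_seg2(t[s2] - dur)); eps[s2] <- -d_eps }
  list(wx = wx, eps = eps)
}

#' Unconfined-compression stress: biphasic radial flow + viscoelastic overlay
#'
#' Linear biphasic unconfined compression of a cylinder (radius a) between
#' frictionless impermeable platens with free draining at the lateral
#' surface. The radial problem reduces to
#' \eqn{\phi_t = H_A k_r (1/r)(r\phi_r)_r - \dot\epsilon_z} with
#' \eqn{\phi = (1/r)\partial(ru)/\partial r} and an elastic boundary
#' condition at r = a; it is discretized once in r and integrated exactly in
#' time by eigendecomposition. The axial stress is
#' \eqn{\sigma_z = 2\mu_s(\epsilon_z - \bar\phi)}, which reproduces the
#' instantaneous (\eqn{3\mu_s\epsilon}) and drained (\eqn{E\epsilon}) limits
#' of the continuum problem exactly. Each strain increment's response is
#' multiplied by a quasi-linear viscoelastic overlay
#' \eqn{1 + c\, e^{-(t - t_{ramp})/\tau_v}}, \eqn{\tau_v = \mu/E}.
#'
#' @param e_young Equilibrium Young's modulus E (MPa).
#' @param nu Drained Poisson ratio, in \[0, 0.5).
#' @param k_r Radial permeability (1e-15 m^4/(N s)).
#' @param c_visc Viscoelastic overlay magnitude (>= 0).
#' @param mu_visc Viscoelastic dashpot viscosity (MPa s); the overlay time
#'   constant is `mu_visc / e_young`.
#' @param geometry A [specimen_geometry()].
#' @param ramps data.frame with one row per ramp: `t0` (start, s),
#'   `duration` (s), `d_strain` (compressive strain increment).
#' @param times Output times (s).
#' @param n_nodes Radial grid size.
#' @return Compressive axial stress (MPa) at `times`.
#' @export
unconfined_forward <- function(e_young, nu, k_r, c_visc, mu_visc,
                               geometry, ramps, times, n_nodes = 40L) {
  stopifnot_scalar(e_young, "e_young", positive = TRUE)
  if (nu < 0 || nu >= 0.5) stop("nu must lie in [0, 0.5)")
  stopifnot_scalar(k_r, "k_r", positive = TRUE)
  if (c_visc < 0) stop("c_visc must be >= 0")
  sys <- unconfined_system(e_young, nu, k_r, geometry, n = n_nodes)
  tau_v <- if (c_visc > 0) mu_visc / e_young else Inf
  sigma <- numeric(length(times))
  for (i in seq_len(nrow(ramps))) {
    tr <- times - ramps$t0[i]
    act <- tr >= 0
    if (!any(act)) next
    resp <- ramp_mode_response(sys, ramps$d_strain[i], ramps$duration[i], tr[act])
    inc <- 2 * sys$mu_s * (resp$eps - resp$wx)   # signed (negative) stress
    overlay <- 1 + c_visc * exp(-tr[act] / tau_v)
    sigma[act] <- sigma[act] + (-inc) * overlay
  }
  sigma / MPA
}

# --- Darcy -----------------------------------------------------------------

#' Simulated steady-state permeametry record
#'
#' Emits the steady flow rate `Q = k_a * dP * S / (l * mu)` through a
#' saturated sample held at a fixed pressure difference, together with the
#' recorded geometry and fluid viscosity.
#'
#' @param k_a Axial permeability (1e-15 m^4/(N s)).
#' @param geometry A [specimen_geometry()]; `thickness` is the flow length.
#' @param delta_p Pressure difference across the sample (Pa), > 0.
#' @param fluid_viscosity Dynamic viscosity (N s/m^2).
#' @return A `darcy_record`: list(q, delta_p, length, area, fluid_viscosity),
#'   all SI.
#' @export
simulate_darcy_test <- function(k_a, geometry = specimen_geometry(),
                                delta_p = 40e3, fluid_viscosity = 1e-3) {
  stopifnot_scalar(k_a, "k_a", positive = TRUE)
  stopifnot_scalar(delta_p, "delta_p", positive = TRUE)
  stopifnot_scalar(fluid_viscosity, "fluid_viscosity", positive = TRUE)
  k <- k_a * KPERM
  q <- k * delta_p * geometry$area_m2 / (geometry$thickness_m * fluid_viscosity)
  structure(list(q = q, delta_p = delta_p, length = geometry$thickness_m,
                 area = geometry$area_m2, fluid_viscosity = fluid_viscosity),
            class = "darcy_record")
}

#' Darcy permeability from a permeametry record
#'
#' `k = Q l mu / (dP S)`.
#'
#' @param record A `darcy_record` (or list with fields q, delta_p, length,
#'   area, fluid_viscosity in SI units).
#' @return list with `k` (m^4/(N s)) and `k_report` (units of 1e-15).
#' @examples
#' darcy_permeability(simulate_darcy_test(10))$k_report  # 10
#' @export
darcy_permeability <- function(record) {
  with(record, {
    if (delta_p <= 0) stop("delta_p must be > 0")
    if (area <= 0 || length <= 0) stop("geometry must be positive")
    if (fluid_viscosity <= 0) stop("fluid_viscosity must be > 0")
    k <- q * length * fluid_viscosity / (delta_p * area)
    list(k = k, k_report = k / KPERM)
  })
}
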