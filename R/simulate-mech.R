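# Generators for the three mechanical experiments. Holds are terminated by
# the same equilibrium criterion the analysis uses: a rolling slope of the
# force falling below 0.1 g/min.

#' Mechanical ground truth for the test generators
#'
#' Defaults are patterned on healthy (in-situ) nucleus pulposus values:
#' E = 0.019 MPa, k_r = 32, H_A0 = 0.12 MPa, k_0 = 15, k_a = 10
#' (permeabilities in 1e-15 m^4/(N s)); the parameters the study does not
#' tabulate (nu, c, mu, beta, M) default to values typical for disc tissue.
#'
#' @param e_young Young's modulus E (MPa).
#' @param mu_visc Viscoelastic dashpot viscosity (MPa s).
#' @param k_r Radial permeability (1e-15 m^4/(N s)).
#' @param nu Drained Poisson ratio in \[0, 0.5).
#' @param c_visc Viscoelastic overlay magnitude (unitless, >= 0).
#' @param h_a0 Zero-strain aggregate modulus (MPa).
#' @param k_0 Zero-strain axial permeability (1e-15 m^4/(N s)).
#' @param beta Aggregate-modulus strain coefficient (unitless).
#' @param m_perm Permeability strain coefficient (unitless).
#' @param k_a Directly measured axial permeability (1e-15 m^4/(N s)).
#' @return An object of class `mech_truth`.
#' @export
mech_truth <- function(e_young = 0.019, mu_visc = 0.57, k_r = 32, nu = 0.1,
                       c_visc = 0.3, h_a0 = 0.12, k_0 = 15, beta = 0.5,
                       m_perm = 0.5, k_a = 10) {
  for (nm in c("e_young", "mu_visc", "k_r", "h_a0", "k_0", "k_a"))
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  if (nu < 0 || nu >= 0.5) stop("nu must lie in [0, 0.5)")
  if (c_visc < 0) stop("c_visc must be >= 0")
  structure(list(e_young = e_young, mu_visc = mu_visc, k_r = k_r, nu = nu,
                 c_visc = c_visc, h_a0 = h_a0, k_0 = k_0, beta = beta,
                 m_perm = m_perm, k_a = k_a), class = "mech_truth")
}

new_mech_curve <- function(t, force, displacement, geometry, schedule, test) {
  if (is.unsorted(t, strictly = TRUE)) stop("time must be strictly increasing")
  structure(list(t = t, force = force, displacement = displacement,
                 geometry = geometry, schedule = schedule, test = test),
            class = "mech_curve")
}

# rolling centered slope of force (N/s); returns NA where the window is not
# fully contained in the data
rolling_slope <- function(t, force, window = 300) {
  n <- length(t)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sel <- which(t >= t[i] - window / 2 & t <= t[i] + window / 2)
    if (t[sel[1]] > t[i] - window / 2 + 1e-9 ||
        t[sel[length(sel)]] < t[i] + window / 2 - 1e-9) next
    if (length(sel) < 3) next
    tt <- t[sel] - t[i]
    out[i] <- sum(tt * (force[sel] - mean(force[sel]))) / sum(tt^2)
  }
  out
}

# first hold index meeting the 0.1 g/min criterion; list(index, met)
hold_cut <- function(t, force, slope_threshold = 0.1, window = 300) {
  thr <- slope_threshold * GRAM_FORCE_N / 60     # g/min -> N/s
  sl <- rolling_slope(t, force, window)
  ok <- which(!is.na(sl) & abs(sl) < thr)
  if (length(ok) == 0) list(index = length(t), met = FALSE)
  else list(index = ok[1], met = TRUE)
}

#' Simulate a confined-compression stress-relaxation test
#'
#' Forward-solves the nonlinear biphasic consolidation model
#' ([confined_forward_nonlinear()]) through successive 5% strain ramps, each
#' followed by a relaxation that ends when the rolling force slope drops
#' below the equilibrium criterion.
#'
#' @param truth A [mech_truth()].
#' @param geometry A [specimen_geometry()].
#' @param n_ramps Number of ramps.
#' @param strain_increment Compressive strain per ramp.
#' @param ramp_duration Ramp time (s).
#' @param max_hold Maximum relaxation time per ramp (s).
#' @param dt_ramp,dt_hold Sampling intervals (s).
#' @param slope_threshold Equilibrium criterion (g/min).
#' @param window Rolling-slope window (s).
#' @param noise_sd Gaussian force noise SD (N); 0 = noiseless.
#' @param seed Seed for the noise draws.
#' @param n_nodes Spatial grid of the solver.
#' @return A `mech_curve` (t s, force N, displacement mm, schedule).
#' @export
simulate_confined_test <- function(truth, geometry = specimen_geometry(),
                                   n_ramps = 5L, strain_increment = 0.05,
                                   ramp_duration = 60, max_hold = 3600,
                                   dt_ramp = 2, dt_hold = 5,
                                   slope_threshold = 0.1, window = 300,
                                   noise_sd = 0, seed = NULL,
                                   n_nodes = 101L) {
  state <- rep(0, n_nodes)
  strain_prev <- 0
  fields_last <- NULL
  # holds are truncated by the criterion after solving, so the carried state
  # is re-anchored from the stored strain fields at the cut index
  seg_solver <- function(t0, t1, times, target) {
    sched <- data.frame(t = c(t0, t1), strain = c(strain_prev, target))
    res <- confined_forward_nonlinear(truth$h_a0, truth$k_0, truth$beta,
                                      truth$m_perm, geometry, sched, times,
                                      n_nodes = n_nodes, y0 = state,
                                      full = TRUE)
    fields_last <<- attr(res, "fields")
    as.numeric(res)
  }
  advance <- function(times, end_i, target) {
    state <<- fields_last[end_i, ]
    strain_prev <<- target
  }
  # sequential simulation with criterion-based truncation
  t_all <- numeric(0); stress_all <- numeric(0); strain_all <- numeric(0)
  sched_t <- 0; sched_strain <- 0
  t_cur <- 0; flags <- logical(n_ramps)
  for (j in seq_len(n_ramps)) {
    target <- strain_prev + strain_increment
    tt <- seq(t_cur + dt_ramp, t_cur + ramp_duration, by = dt_ramp)
    ramp <- seg_solver(t_cur, t_cur + ramp_duration, tt, target)
    advance(tt, length(tt), target)
    frac <- (tt - t_cur) / ramp_duration
    t_all <- c(t_all, tt); stress_all <- c(stress_all, ramp)
    strain_all <- c(strain_all, target - strain_increment + frac * strain_increment)
    t_cur <- t_cur + ramp_duration
    sched_t <- c(sched_t, t_cur); sched_strain <- c(sched_strain, target)
    th <- seq(t_cur + dt_hold, t_cur + max_hold, by = dt_hold)
    hold <- seg_solver(t_cur, t_cur + max_hold, th, target)
    cut <- hold_cut(th, hold * geometry$area_m2 * MPA, slope_threshold, window)
    flags[j] <- !cut$met
    end_i <- min(length(th), cut$index + ceiling(window / 2 / dt_hold))
    advance(th, end_i, target)
    t_all <- c(t_all, th[seq_len(end_i)])
    stress_all <- c(stress_all, hold[seq_len(end_i)])
    strain_all <- c(strain_all, rep(target, end_i))
    t_cur <- th[end_i]
    sched_t <- c(sched_t, t_cur); sched_strain <- c(sched_strain, target)
  }
  force <- stress_all * MPA * geometry$area_m2
  if (noise_sd > 0)
    force <- with_seed(seed, force + stats::rnorm(length(force), 0, noise_sd))
  curve <- new_mech_curve(t_all, force, strain_all * geometry$thickness,
                          geometry,
                          data.frame(t = sched_t, strain = sched_strain),
                          test = "confined")
  attr(curve, "criterion_never_met") <- flags
  curve
}

#' Simulate an unconfined-compression stress-relaxation test
#'
#' Five (by default) successive 5%-strain ramps of the linear biphasic
#' radial-flow model with viscoelastic overlay ([unconfined_forward()]);
#' each relaxation ends at the rolling-slope equilibrium criterion.
#'
#' @inheritParams simulate_confined_test
#' @return A `mech_curve`.
#' @export
simulate_unconfined_test <- function(truth, geometry = specimen_geometry(),
                                     n_ramps = 5L, strain_increment = 0.05,
                                     ramp_duration = 60, max_hold = 3600,
                                     dt_ramp = 2, dt_hold = 5,
                                     slope_threshold = 0.1, window = 300,
                                     noise_sd = 0, seed = NULL,
                                     n_nodes = 40L) {
  ramps <- data.frame(t0 = numeric(0), duration = numeric(0),
                      d_strain = numeric(0))
  stress_at <- function(times) {
    unconfined_forward(truth$e_young, truth$nu, truth$k_r, truth$c_visc,
                       truth$mu_visc, geometry, ramps, times,
                       n_nodes = n_nodes)
  }
  t_all <- numeric(0); stress_all <- numeric(0); strain_all <- numeric(0)
  sched_t <- 0; sched_strain <- 0
  t_cur <- 0; strain_cur <- 0; flags <- logical(n_ramps)
  for (j in seq_len(n_ramps)) {
    ramps <- rbind(ramps, data.frame(t0 = t_cur, duration = ramp_duration,
                                     d_strain = strain_increment))
    tt <- seq(t_cur + dt_ramp, t_cur + ramp_duration, by = dt_ramp)
    t_all <- c(t_all, tt); stress_all <- c(stress_all, stress_at(tt))
    strain_all <- c(strain_all,
                    strain_cur + (tt - t_cur) / ramp_duration * strain_increment)
    t_cur <- t_cur + ramp_duration
    strain_cur <- strain_cur + strain_increment
    sched_t <- c(sched_t, t_cur); sched_strain <- c(sched_strain, strain_cur)
    th <- seq(t_cur + dt_hold, t_cur + max_hold, by = dt_hold)
    hold <- stress_at(th)
    cut <- hold_cut(th, hold * MPA * geometry$area_m2, slope_threshold, window)
    flags[j] <- !cut$met
    end_i <- min(length(th), cut$index + ceiling(window / 2 / dt_hold))
    t_all <- c(t_all, th[seq_len(end_i)])
    stress_all <- c(stress_all, hold[seq_len(end_i)])
    strain_all <- c(strain_all, rep(strain_cur, end_i))
    t_cur <- th[end_i]
    sched_t <- c(sched_t, t_cur); sched_strain <- c(sched_strain, strain_cur)
  }
  force <- stress_all * MPA * geometry$area_m2
  if (noise_sd > 0)
    force <- with_seed(seed, force + stats::rnorm(length(force), 0, noise_sd))
  curve <- new_mech_curve(t_all, force, strain_all * geometry$thickness,
                          geometry,
                          data.frame(t = sched_t, strain = sched_strain),
                          test = "unconfined")
  attr(curve, "criterion_never_met") <- flags
  curve
}
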