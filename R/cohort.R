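# Cohort generator: 4 experimental groups (in-situ and three trypsin
# digestion durations) x 2 disc regions, with MRI variables drawn from the
# published group tables and mechanical properties produced by the linear
# MRI -> mechanics linkage.

GROUPS <- c("in-situ", "dig6h", "dig18h", "dig24h")
REGIONS <- c("NP", "AF")
MRI_VARS <- c("T1", "T2", "MTR", "ADC", "FA")
MECH_VARS <- c("E", "k_r", "H_A0", "k_0", "k_a")

# group means/SDs, reporting units (T1/T2 ms, MTR x100, FA x100,
# ADC x1e-4 mm^2/s; E/H_A0 MPa, permeabilities 1e-15 m^4/(N s))
default_mri_table <- function() {
  d <- rbind(
    c("NP", "in-situ", 1140, 76, 124, 16, 34, 20, 15.04, 0.62,  8.03, 4.59),
    c("NP", "dig6h",   1056, 130,  87, 26, 28, 15, 15.25, 1.58, 18.59, 6.67),
    c("NP", "dig18h",  1115, 130, 123,  5, 33, 24, 14.79, 1.13,  8.15, 4.52),
    c("NP", "dig24h",  1144, 78,  118,  7, 32, 22, 14.17, 0.84, 13.03, 7.08),
    c("AF", "in-situ",  706, 44,   70, 11, 44, 15, 15.89, 1.06, 15.83, 3.05),
    c("AF", "dig6h",    659, 71,   62, 11, 38, 13, 16.87, 0.95, 23.87, 5.24),
    c("AF", "dig18h",   663, 73,   65,  5, 42, 18, 15.34, 1.27, 17.10, 4.60),
    c("AF", "dig24h",   710, 85,   68,  5, 42, 16, 15.42, 1.13, 20.89, 4.93))
  out <- data.frame(region = d[, 1], group = d[, 2],
                    apply(d[, -(1:2)], 2, as.numeric))
  names(out)[-(1:2)] <- c("T1_mean", "T1_sd", "T2_mean", "T2_sd",
                          "MTR_mean", "MTR_sd", "ADC_mean", "ADC_sd",
                          "FA_mean", "FA_sd")
  out
}

default_mech_table <- function() {
  d <- rbind(
    c("NP", "in-situ", 0.019, 0.017,  32,  27, 0.12, 0.08, 15, 17, 10, 2),
    c("NP", "dig6h",   0.008, 0.007,  74,  40, 0.04, 0.04, 31, 15, 13, 3),
    c("NP", "dig18h",  0.012, 0.015, 111, 154, 0.03, 0.03, 26, 19, 14, 2),
    c("NP", "dig24h",  0.007, 0.008, 218, 210, 0.02, 0.01, 40, 22, 16, 3),
    c("AF", "in-situ", 0.035, 0.030,  11,   8, 0.22, 0.17, 20, 27,  8, 4),
    c("AF", "dig6h",   0.029, 0.019,  12,  17, 0.09, 0.06, 11, 16,  7, 2),
    c("AF", "dig18h",  0.023, 0.018,  21,  16, 0.04, 0.03, 37, 28,  7, 2),
    c("AF", "dig24h",  0.012, 0.013,  59,  58, 0.07, 0.06,  9,  8,  9, 2))
  out <- data.frame(region = d[, 1], group = d[, 2],
                    apply(d[, -(1:2)], 2, as.numeric))
  names(out)[-(1:2)] <- c("E_mean", "E_sd", "k_r_mean", "k_r_sd",
                          "H_A0_mean", "H_A0_sd", "k_0_mean", "k_0_sd",
                          "k_a_mean", "k_a_sd")
  out
}

# linkage coefficients (a0..a5) per region x property such that the linkage
# maps the group-mean MRI vector exactly onto the group-mean mechanical
# value. The minimum-norm solution is taken on standardized predictors
# (z-scored with the pooled within-group SD) and mapped back to raw units:
# this keeps the within-group mechanical variance the linkage propagates
# from the MRI scatter as small as the group-mean constraints allow.
default_linkage <- function(mri_table = default_mri_table(),
                            mech_table = default_mech_table()) {
  out <- list()
  for (rg in unique(mri_table$region)) {
    mri <- mri_table[mri_table$region == rg, ]
    mech <- mech_table[mech_table$region == rg, ]
    X <- as.matrix(mri[paste0(MRI_VARS, "_mean")])
    m0 <- colMeans(X)
    s0 <- colMeans(as.matrix(mri[paste0(MRI_VARS, "_sd")]))
    Z <- cbind(1, sweep(sweep(X, 2, m0), 2, s0, "/"))
    coefs <- sapply(MECH_VARS, function(mp) {
      az <- as.vector(pinv(Z) %*% mech[[paste0(mp, "_mean")]])
      a <- az[-1] / s0
      c(az[1] - sum(az[-1] * m0 / s0), a)
    })
    rownames(coefs) <- c("a0", "a1", "a2", "a3", "a4", "a5")
    out[[rg]] <- coefs
  }
  out
}

#' Specification of a synthetic disc cohort
#'
#' Defines the study design the cohort generator emulates: four groups
#' (in-situ plus 6 h / 18 h / 24 h trypsin digestion) by two regions
#' (nucleus pulposus NP, annulus fibrosus AF), n per group, the group
#' mean/SD tables of the five MRI and five mechanical variables, and the
#' linear linkage `MP = a0 + a1 T1 + a2 T2 + a3 MTR + a4 ADC + a5 FA` that
#' generates mechanical properties from MRI draws.
#'
#' @param n_per_group Samples per group (>= 2), default 15.
#' @param mri_table data.frame of per-region, per-group MRI means/SDs
#'   (reporting units); default: the published group table.
#' @param mech_table Same for the mechanical properties.
#' @param linkage Named list (per region) of 6 x 5 coefficient matrices
#'   (a0..a5 by E, k_r, H_A0, k_0, k_a); default: minimum-norm coefficients
#'   that reproduce the mech_table group means from the mri_table group
#'   means.
#' @param noise_sd Residual SD of the linkage per property; a named vector
#'   over E, k_r, H_A0, k_0, k_a, or a single fraction interpreted relative
#'   to each property's across-group mean (default 0.10).
#' @param mech_mode `"linkage"` (mechanical values from the linkage) or
#'   `"direct"` (drawn from mech_table Gaussians, used for
#'   constructed-separation studies).
#' @param sd_scale Multiplier on all table SDs (separation control).
#' @param truncate Truncate physically positive variables at 0.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 15L,
                        mri_table = default_mri_table(),
                        mech_table = default_mech_table(),
                        linkage = NULL,
                        noise_sd = 0.10,
                        mech_mode = c("linkage", "direct"),
                        sd_scale = 1,
                        truncate = TRUE,
                        seed = 1L) {
  mech_mode <- match.arg(mech_mode)
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  sd_cols <- grep("_sd$", names(mri_table), value = TRUE)
  if (any(mri_table[sd_cols] < 0)) stop("SDs must be >= 0")
  if (is.null(linkage)) linkage <- default_linkage(mri_table, mech_table)
  if (length(noise_sd) == 1 && is.null(names(noise_sd))) {
    frac <- noise_sd
    noise_sd <- lapply(stats::setNames(REGIONS, REGIONS), function(rg) {
      m <- mech_table[mech_table$region == rg, ]
      stats::setNames(vapply(MECH_VARS, function(mp)
        frac * mean(m[[paste0(mp, "_mean")]]), numeric(1)), MECH_VARS)
    })
  } else {
    if (any(unlist(noise_sd) < 0)) stop("noise_sd must be >= 0")
    noise_sd <- lapply(stats::setNames(REGIONS, REGIONS),
                       function(rg) stats::setNames(noise_sd[MECH_VARS], MECH_VARS))
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 mri_table = mri_table, mech_table = mech_table,
                 linkage = linkage, noise_sd = noise_sd,
                 mech_mode = mech_mode, sd_scale = sd_scale,
                 truncate = truncate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort table
#'
#' Draws the five MRI variables per group x region from Gaussians with the
#' spec's means and SDs, then produces each mechanical property either from
#' the linear linkage plus Gaussian residual noise (`mech_mode = "linkage"`)
#' or from the mechanical group table (`"direct"`). Physically positive
#' quantities are truncated at 0 (the truncated count is recorded as an
#' attribute). Fully reproducible under the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame with columns sample_id, group, region, T1_ms, T2_ms,
#'   MTR, ADC, FA, E, k_r, H_A0, k_0, k_a (reporting units), with
#'   attributes `linkage`, `n_truncated`.
#' @examples
#' head(simulate_cohort(cohort_spec(n_per_group = 3)))
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    rows <- list()
    n_trunc <- 0L
    for (rg in REGIONS) {
      mri <- spec$mri_table[spec$mri_table$region == rg, ]
      mech <- spec$mech_table[spec$mech_table$region == rg, ]
      for (g in GROUPS) {
        mrow <- mri[mri$group == g, ]
        krow <- mech[mech$group == g, ]
        n <- spec$n_per_group
        Xm <- sapply(MRI_VARS, function(v)
          stats::rnorm(n, mrow[[paste0(v, "_mean")]],
                       spec$sd_scale * mrow[[paste0(v, "_sd")]]))
        Xm <- matrix(Xm, nrow = n,
                     dimnames = list(NULL, MRI_VARS))
        if (spec$truncate) {
          bad <- Xm < 0
          n_trunc <- n_trunc + sum(bad)
          Xm[bad] <- 0
        }
        if (spec$mech_mode == "linkage") {
          A <- spec$linkage[[rg]]
          Mp <- cbind(1, Xm) %*% A
          for (mp in MECH_VARS)
            Mp[, mp] <- Mp[, mp] +
              stats::rnorm(n, 0, spec$noise_sd[[rg]][[mp]])
        } else {
          Mp <- sapply(MECH_VARS, function(v)
            stats::rnorm(n, krow[[paste0(v, "_mean")]],
                         spec$sd_scale * krow[[paste0(v, "_sd")]]))
          Mp <- matrix(Mp, nrow = n, dimnames = list(NULL, MECH_VARS))
        }
        if (spec$truncate) {
          bad <- Mp < 0
          n_trunc <- n_trunc + sum(bad)
          Mp[bad] <- 0
        }
        rows[[paste(rg, g)]] <- data.frame(
          sample_id = sprintf("%s_%s_%02d", rg, g, seq_len(n)),
          group = g, region = rg,
          T1_ms = Xm[, "T1"], T2_ms = Xm[, "T2"], MTR = Xm[, "MTR"],
          ADC = Xm[, "ADC"], FA = Xm[, "FA"],
          E = Mp[, "E"], k_r = Mp[, "k_r"], H_A0 = Mp[, "H_A0"],
          k_0 = Mp[, "k_0"], k_a = Mp[, "k_a"])
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "linkage") <- spec$linkage
    attr(out, "n_truncated") <- n_trunc
    out
  })
}

# map cohort column names to the regression variable names
cohort_predictors <- function(cohort) {
  d <- cohort
  names(d)[names(d) == "T1_ms"] <- "T1"
  names(d)[names(d) == "T2_ms"] <- "T2"
  d
}
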