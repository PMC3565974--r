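# Orchestration: one seeded, reproducible run of
# simulate -> fit-mri -> fit-mech -> analyze with plain-text outputs.

#' Study configuration
#'
#' Bundles everything a full run needs; round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param seed Master seed.
#' @param n_per_group Cohort size per group.
#' @param noise_sd Linkage residual fraction (see [cohort_spec()]).
#' @param mech_mode,sd_scale,truncate Passed to [cohort_spec()].
#' @param phantom_shape Integer 2-vector; grid of the exemplar phantom.
#' @param phantom_noise_sigma Rician sigma of the phantom stacks.
#' @param mech_exemplars Simulate-and-fit exemplar mechanical tests
#'   (unconfined, confined, permeametry) for one specimen.
#' @param mech_n_ramps,mech_n_nodes Size of the exemplar mechanical tests.
#' @param vif_threshold VIF elimination threshold.
#' @param ncp_convention Power noncentrality convention.
#' @param k_override Fixed cluster count (NULL = natural division).
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed = 1L, n_per_group = 15L, noise_sd = 0.10,
                         mech_mode = "linkage", sd_scale = 1,
                         truncate = TRUE,
                         phantom_shape = c(4L, 4L),
                         phantom_noise_sigma = 0,
                         mech_exemplars = FALSE,
                         mech_n_ramps = 2L, mech_n_nodes = 61L,
                         vif_threshold = 10, ncp_convention = "n",
                         k_override = NULL) {
  structure(list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
                 noise_sd = noise_sd, mech_mode = mech_mode,
                 sd_scale = sd_scale, truncate = truncate,
                 phantom_shape = as.integer(phantom_shape),
                 phantom_noise_sigma = phantom_noise_sigma,
                 mech_exemplars = isTRUE(mech_exemplars),
                 mech_n_ramps = as.integer(mech_n_ramps),
                 mech_n_nodes = as.integer(mech_n_nodes),
                 vif_threshold = vif_threshold,
                 ncp_convention = ncp_convention,
                 k_override = k_override),
            class = "study_config")
}

#' @rdname study_config
#' @param config A `study_config`.
#' @param file YAML path.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname study_config
#' @export
read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(study_config, raw[!vapply(raw, is.null, logical(1))])
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Full statistical analysis of one region's cohort slice
#'
#' Reproduces the study's statistics layer: group mean/SD summaries, one-way
#' ANOVA with Dunn-Sidak pairwise comparisons for every variable, per-group
#' multiple linear regressions of each mechanical property on the five MRI
#' parameters (with R-squared, SEE, power, VIF), pooled VIF elimination, a
#' PCA per mechanical property (that property plus the five MRI parameters),
#' and Ward clustering with natural-division detection on the first three
#' principal components of the mechanical properties and of the MRI
#' parameters.
#'
#' @param cohort Cohort data.frame.
#' @param region `"NP"` or `"AF"`.
#' @param vif_threshold VIF elimination threshold.
#' @param ncp_convention Power convention, see [regression_power()].
#' @param k_override Fixed cluster count (NULL = natural division).
#' @return list with `summary`, `anova`, `regressions`, `vif_elimination`,
#'   `pca`, `clustering`.
#' @export
analyze_cohort <- function(cohort, region = "NP", vif_threshold = 10,
                           ncp_convention = "n", k_override = NULL) {
  d <- cohort_predictors(cohort[cohort$region == region, , drop = FALSE])
  if (nrow(d) == 0) stop("no rows for region ", region)
  vars <- c(MRI_VARS, MECH_VARS)

  summary_tab <- do.call(rbind, lapply(GROUPS, function(g) {
    dg <- d[d$group == g, ]
    row <- data.frame(region = region, group = g, n = nrow(dg))
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- mean(dg[[v]], na.rm = TRUE)
      row[[paste0(v, "_sd")]] <- stats::sd(dg[[v]], na.rm = TRUE)
    }
    row
  }))

  anova_tab <- do.call(rbind, lapply(vars, function(v) {
    a <- one_way_anova(d[[v]], d$group)
    ph <- dunn_sidak_pairwise(d[[v]], d$group)
    data.frame(variable = v,
               comparison = c("global", paste(ph$group1, ph$group2, sep = "/")),
               p = c(a$p, ph$p_adjusted))
  }))

  regressions <- list()
  for (g in GROUPS) {
    dg <- d[d$group == g, ]
    for (mp in MECH_VARS) {
      key <- paste(g, mp, sep = ".")
      regressions[[key]] <- tryCatch(
        fit_multilinear(dg, mp, ncp_convention = ncp_convention),
        error = function(e) NULL)
    }
  }
  reg_tab <- do.call(rbind, lapply(names(regressions), function(k) {
    r <- regressions[[k]]
    if (is.null(r)) return(NULL)
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(region = region, group = parts[1], response = parts[2],
               r2 = r$r2, see = r$see, power = r$power, n = r$n)
  }))

  vif_elim <- lapply(stats::setNames(MECH_VARS, MECH_VARS), function(mp)
    vif_eliminate(d, mp, threshold = vif_threshold))

  pca <- lapply(stats::setNames(MECH_VARS, MECH_VARS), function(mp) {
    run_pca(as.matrix(d[c(mp, MRI_VARS)]))
  })

  clust <- lapply(stats::setNames(c("mech", "mri"), c("mech", "mri")),
                  function(which_set) {
    cols <- if (which_set == "mech") MECH_VARS else MRI_VARS
    p <- run_pca(as.matrix(d[cols]))
    sc <- p$scores[, 1:3, drop = FALSE]
    rownames(sc) <- d$sample_id
    tree <- ward_cluster(sc)
    div <- natural_division(tree)
    if (!is.null(k_override)) {
      div$k <- as.integer(k_override)
      div$assignments <- stats::setNames(
        stats::cutree(as_hclust(tree), k = div$k), tree$labels)
    }
    list(pca = p, tree = tree, division = div,
         groups = stats::setNames(d$group, d$sample_id))
  })

  list(summary = summary_tab, anova = anova_tab,
       regressions = reg_tab, regression_fits = regressions,
       vif_elimination = vif_elim, pca = pca, clustering = clust)
}

#' Run the full study pipeline
#'
#' simulate -> fit-mri -> fit-mech -> analyze, writing every stage output as
#' plain text into a fresh run directory along with a manifest (config hash,
#' seed, package version). Rerunning with the same config reproduces all
#' tables byte-identically.
#'
#' @param config A [study_config()].
#' @param out_dir Parent directory for the run.
#' @param run_name Subdirectory name; default derived from the config hash.
#' @return list with `dir` (the run directory), `cohort`, `analysis`
#'   (per-region results of [analyze_cohort()]), and (if enabled)
#'   `mri_summary`, `mech_fits`.
#' @export
run_study <- function(config = study_config(), out_dir = "runs",
                      run_name = NULL) {
  hash <- config_hash(config)
  if (is.null(run_name)) run_name <- paste0("run-", substr(hash, 1, 8))
  dir <- file.path(out_dir, run_name)
  if (dir.exists(dir)) stop("run directory already exists: ", dir)
  dir.create(dir, recursive = TRUE)
  stage <- "simulate"
  res <- try({
    write_config(config, file.path(dir, "config.yaml"))

    # --- simulate ---
    spec <- cohort_spec(n_per_group = config$n_per_group,
                        noise_sd = config$noise_sd,
                        mech_mode = config$mech_mode,
                        sd_scale = config$sd_scale,
                        truncate = config$truncate,
                        seed = config$seed)
    cohort <- simulate_cohort(spec)
    write_cohort_csv(cohort, file.path(dir, "cohort.csv"))

    truths <- list(
      NP = tissue_truth(1140, 124, 0.34, tensor_from_md_fa(15.04e-4, 0.0803)),
      AF = tissue_truth(706, 70, 0.44, tensor_from_md_fa(15.89e-4, 0.1583)))
    phantom <- simulate_phantom(config$phantom_shape, truths,
                                noise_sigma = config$phantom_noise_sigma,
                                seed = config$seed + 1L)
    write_phantom_csv(phantom, file.path(dir, "phantom_voxels.csv"))

    mech_fits <- NULL
    if (config$mech_exemplars) {
      truth <- mech_truth()
      cu <- simulate_unconfined_test(truth, n_ramps = config$mech_n_ramps,
                                     n_nodes = 40L)
      cc <- simulate_confined_test(truth, n_ramps = config$mech_n_ramps,
                                   n_nodes = config$mech_n_nodes)
      da <- simulate_darcy_test(truth$k_a)
      write_mech_curve(cu, file.path(dir, "unconfined_NP.csv"))
      write_mech_curve(cc, file.path(dir, "confined_NP.csv"))
      jsonlite::write_json(unclass(da), file.path(dir, "darcy_NP.json"),
                           auto_unbox = TRUE, digits = NA)
    }

    # --- fit-mri ---
    stage <- "fit-mri"
    maps <- fit_voxelwise(phantom$voxels, phantom$protocol)
    mri_summary <- roi_aggregate(maps)
    utils::write.csv(maps, file.path(dir, "parameter_maps.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(mri_summary, file.path(dir, "roi_summary.csv"),
                     row.names = FALSE, quote = FALSE)

    # --- fit-mech ---
    stage <- "fit-mech"
    if (config$mech_exemplars) {
      fu <- fit_unconfined(read_mech_curve(file.path(dir, "unconfined_NP.csv")))
      fc <- fit_confined(read_mech_curve(file.path(dir, "confined_NP.csv")),
                         n_nodes = config$mech_n_nodes)
      da <- jsonlite::read_json(file.path(dir, "darcy_NP.json"),
                                simplifyVector = TRUE)
      ka <- darcy_permeability(da)
      mech_fits <- data.frame(
        parameter = c("E", "mu", "k_r", "nu", "c", "H_A0", "k_0", "beta",
                      "M", "k_a"),
        value = c(fu$e_young, fu$mu_visc, fu$k_r, fu$nu, fu$c_visc,
                  fc$h_a0, fc$k_0, fc$beta, fc$m_perm, ka$k_report))
      utils::write.csv(mech_fits, file.path(dir, "mech_fits.csv"),
                       row.names = FALSE, quote = FALSE)
    }

    # --- analyze ---
    stage <- "analyze"
    analysis <- lapply(stats::setNames(REGIONS, REGIONS), function(rg)
      analyze_cohort(cohort, rg, vif_threshold = config$vif_threshold,
                     ncp_convention = config$ncp_convention,
                     k_override = config$k_override))
    write_report(analysis, dir)

    manifest <- data.frame(key = c("config_hash", "seed", "package_version"),
                           value = c(hash, config$seed,
                                     as.character(utils::packageVersion("discmech"))))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    list(dir = dir, cohort = cohort, analysis = analysis,
         mri_summary = mri_summary, mech_fits = mech_fits)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop(sprintf("pipeline failed at stage '%s' (partial outputs in %s): %s",
                 stage, dir, attr(res, "condition")$message))
  res
}

#' Write the analysis report bundle
#'
#' Renders, per region: the mean/SD summary, the ANOVA/post-hoc p-value
#' table, the regression table (R-squared, SEE, power per group x response),
#' the PCA cumulative-variability table, correlation-circle coordinates,
#' dendrograms as Newick, and cluster assignments; plus a compact
#' `report.md` overview.
#'
#' @param analysis Named list (per region) of [analyze_cohort()] results.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(analysis, dir) {
  if (length(analysis) == 0 || is.null(names(analysis)))
    stop("missing stage output: analysis list is empty")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- c("# Disc cohort analysis", "")
  for (rg in names(analysis)) {
    a <- analysis[[rg]]
    for (nm in c("summary", "anova", "regressions"))
      if (is.null(a[[nm]]))
        stop("missing stage output for region ", rg, ": ", nm)
    utils::write.csv(a$summary, file.path(dir, paste0("summary_", rg, ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(a$anova, file.path(dir, paste0("anova_", rg, ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(a$regressions,
                     file.path(dir, paste0("regressions_", rg, ".csv")),
                     row.names = FALSE, quote = FALSE)
    pv <- do.call(rbind, lapply(names(a$pca), function(mp)
      data.frame(property = mp, component = paste0("F", 1:3),
                 eigenvalue = a$pca[[mp]]$eigenvalues[1:3],
                 cumulative = a$pca[[mp]]$cumulative_variability[1:3])))
    utils::write.csv(pv, file.path(dir, paste0("pca_variability_", rg, ".csv")),
                     row.names = FALSE, quote = FALSE)
    cc <- do.call(rbind, lapply(names(a$pca), function(mp) {
      xy <- correlation_circle(a$pca[[mp]])
      data.frame(property = mp, variable = rownames(xy),
                 F1 = xy[, 1], F2 = xy[, 2])
    }))
    utils::write.csv(cc, file.path(dir, paste0("correlation_circle_", rg, ".csv")),
                     row.names = FALSE, quote = FALSE)
    for (ws in names(a$clustering)) {
      cl <- a$clustering[[ws]]
      write_dendrogram_newick(cl$tree,
                              file.path(dir, sprintf("dendrogram_%s_%s.nwk",
                                                     rg, ws)))
      utils::write.csv(
        data.frame(sample_id = names(cl$division$assignments),
                   cluster = cl$division$assignments,
                   group = cl$groups[names(cl$division$assignments)]),
        file.path(dir, sprintf("clusters_%s_%s.csv", rg, ws)),
        row.names = FALSE, quote = FALSE)
    }
    md <- c(md, sprintf("## Region %s", rg),
            sprintf("- samples: %d", sum(a$summary$n)),
            sprintf("- natural division (mechanical): %d clusters",
                    a$clustering$mech$division$k),
            sprintf("- natural division (MRI): %d clusters",
                    a$clustering$mri$division$k),
            sprintf("- regressions computed: %d", nrow(a$regressions)), "")
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
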