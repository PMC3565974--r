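# Plain-text interchange: cohort CSV, mechanical curve CSV + JSON sidecar,
# phantom voxel-table CSV (NIfTI export optional via RNifti).

#' Write / read a cohort table
#'
#' One row per sample x region; columns sample_id, group, region, T1_ms,
#' T2_ms, MTR, ADC, FA, E, k_r, H_A0, k_0, k_a.
#'
#' @param cohort Cohort data.frame.
#' @param file Path to CSV.
#' @return `write_cohort_csv`: the path, invisibly. `read_cohort_csv`: the
#'   cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, file) {
  utils::write.csv(cohort, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "region", "T1_ms", "T2_ms", "MTR", "ADC",
            "FA", "E", "k_r", "H_A0", "k_0", "k_a")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("cohort CSV lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(d[c("sample_id", "region")]))
    stop("duplicated (sample_id, region) rows")
  bad <- setdiff(unique(d$group), GROUPS)
  if (length(bad) > 0)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  d
}

#' Write / read a mechanical test curve
#'
#' CSV with columns t_s, force_N, displacement_mm plus a JSON sidecar
#' (same path, `.json` extension) holding geometry, schedule and test type.
#'
#' @param curve A `mech_curve`.
#' @param file Path to the CSV.
#' @return `write_mech_curve`: the path, invisibly. `read_mech_curve`: a
#'   `mech_curve`.
#' @export
write_mech_curve <- function(curve, file) {
  utils::write.csv(data.frame(t_s = curve$t, force_N = curve$force,
                              displacement_mm = curve$displacement),
                   file, row.names = FALSE, quote = FALSE)
  sidecar <- sub("\\.csv$", ".json", file)
  jsonlite::write_json(
    list(test = curve$test,
         geometry = list(radius = curve$geometry$radius,
                         thickness = curve$geometry$thickness),
         schedule = curve$schedule),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_mech_curve
#' @export
read_mech_curve <- function(file) {
  d <- utils::read.csv(file)
  sidecar <- sub("\\.csv$", ".json", file)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  new_mech_curve(d$t_s, d$force_N, d$displacement_mm,
                 specimen_geometry(meta$geometry$radius,
                                   meta$geometry$thickness),
                 as.data.frame(meta$schedule), meta$test)
}

#' Write / read a phantom voxel table
#'
#' Long-format CSV: voxel_id, roi, sequence, index_value, signal.
#'
#' @param phantom A `disc_phantom` (or its `$voxels` data.frame).
#' @param file Path to the CSV.
#' @return `write_phantom_csv`: the path, invisibly. `read_phantom_csv`:
#'   the voxel data.frame.
#' @export
write_phantom_csv <- function(phantom, file) {
  voxels <- if (inherits(phantom, "disc_phantom")) phantom$voxels else phantom
  utils::write.csv(voxels, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_phantom_csv
#' @export
read_phantom_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("voxel_id", "roi", "sequence", "index_value", "signal")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("phantom CSV lacks columns: ", paste(miss, collapse = ", "))
  d
}

#' Export parameter maps of a rectangular phantom as NIfTI volumes
#'
#' One volume per parameter (t1, t2, mtr, adc, fa). Requires the RNifti
#' package.
#'
#' @param maps Output of [fit_voxelwise()].
#' @param labels The phantom's label matrix (defines the grid shape).
#' @param dir Output directory.
#' @return Character vector of file paths, invisibly.
#' @export
write_maps_nifti <- function(maps, labels, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (p in c("t1", "t2", "mtr", "adc", "fa")) {
    img <- matrix(NA_real_, nrow(labels), ncol(labels))
    img[maps$voxel_id] <- maps[[p]]
    path <- file.path(dir, paste0(p, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(img), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
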