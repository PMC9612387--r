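#' Read a dynamic image from NIfTI plus a frame-timing sidecar
#'
#' NIfTI has no standard slot for frame timing, so the schedule travels as a
#' JSON sidecar `{"frame_starts_s": [...], "frame_durations_s": [...]}`.
#'
#' @param path_image Path to a 4D NIfTI file (frame axis last).
#' @param path_schedule Path to the schedule JSON.
#' @return A [dynamic_image()].
#' @export
read_dynamic <- function(path_image, path_schedule) {
  img <- RNifti::readNifti(path_image)
  a <- as.array(img)
  if (length(dim(a)) != 4L) {
    stop(sprintf("expected a 4D image, got %dD", length(dim(a))))
  }
  sj <- jsonlite::read_json(path_schedule, simplifyVector = TRUE)
  if (is.null(sj$frame_durations_s)) {
    stop("schedule JSON lacks frame_durations_s")
  }
  sched <- frame_schedule(sj$frame_durations_s, sj$frame_starts_s)
  if (length(sched) != dim(a)[4]) {
    stop(sprintf("schedule has %d frames but image has %d", length(sched),
                 dim(a)[4]))
  }
  vs <- RNifti::pixdim(img)[1:3]
  dynamic_image(a, sched, vs)
}

#' Read a 3D binary mask from a NIfTI label image
#' @param path Path to a 3D NIfTI; voxels with value > 0 are in the mask.
#' @return Logical 3D array.
#' @export
read_mask <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) != 3L) stop("mask must be a 3D image")
  array(a > 0, dim = dim(a))
}

.write_nifti <- function(a, voxel_size_mm, path, tr = 1) {
  img <- RNifti::asNifti(a)
  nd <- length(dim(a))
  img <- RNifti::`pixdim<-`(img, c(voxel_size_mm, rep(tr, nd - 3)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a synthetic patient to disk
#'
#' Writes the 4D dynamic volume (`dynamic.nii.gz`), the four VOI masks as
#' 3D label images, the frame schedule as a JSON sidecar and the ground
#' truth kinetic parameters as JSON.
#'
#' @param patient A `synthetic_patient` from [simulate_patient()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_patient <- function(patient, dir) {
  stopifnot(inherits(patient, "synthetic_patient"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  di <- patient$dynamic_image
  paths <- c(dynamic = file.path(dir, "dynamic.nii.gz"))
  .write_nifti(di$voxels, di$voxel_size_mm, paths["dynamic"])
  for (nm in c("tumor", "mirrored", "crescent", "ventricle")) {
    p <- file.path(dir, paste0(nm, "_mask.nii.gz"))
    .write_nifti(array(as.integer(patient$voi_set[[paste0(nm, "_mask")]]),
                       dim = dim(di$voxels)[1:3]),
                 di$voxel_size_mm, p)
    paths[nm] <- p
  }
  paths["schedule"] <- file.path(dir, "schedule.json")
  jsonlite::write_json(
    list(frame_starts_s = di$schedule$frame_starts_s,
         frame_durations_s = di$schedule$frame_durations_s),
    paths["schedule"], auto_unbox = FALSE, digits = NA)
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(
    lapply(patient$truth, function(p) unclass(p)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a parametric image as 3D NIfTI
#' @param pimg A [parametric_image()].
#' @param path Output path (`.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_parametric <- function(pimg, path) {
  stopifnot(inherits(pimg, "parametric_image"))
  .write_nifti(pimg$voxels, pimg$voxel_size_mm, path)
}

#' Resolve and persist a pipeline run configuration
#'
#' A run configuration collects simulation, discretization, Wilcoxon and
#' classification settings plus the master seed. The fully resolved
#' configuration is written as JSON next to the outputs and its MD5 hash is
#' stamped on every output table so mixed-config results are detectable.
#'
#' @param out_dir Output directory of the run.
#' @param n_patients,phenotype_mix,seed Cohort settings.
#' @param grid_shape,noise_scale Phantom settings (see [phantom_spec()]).
#' @param bin_count Discretization bins.
#' @param alpha Wilcoxon significance threshold.
#' @param n_repeats,n_folds Nested-CV settings.
#' @param smoothing_window TTP smoothing (frames, odd) or `NULL`.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(out_dir,
                       n_patients = 46L,
                       phenotype_mix = c(isometabolic = 29 / 46,
                                         photopenic = 17 / 46),
                       seed = 1L,
                       grid_shape = c(64L, 64L, 48L),
                       noise_scale = 1,
                       bin_count = 32L,
                       alpha = 0.05,
                       n_repeats = 50L,
                       n_folds = 5L,
                       smoothing_window = NULL) {
  structure(list(out_dir = out_dir, n_patients = as.integer(n_patients),
                 phenotype_mix = as.numeric(phenotype_mix),
                 seed = as.integer(seed), grid_shape = as.integer(grid_shape),
                 noise_scale = noise_scale, bin_count = as.integer(bin_count),
                 alpha = alpha, n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 smoothing_window = smoothing_window),
            class = "run_config")
}

#' Write a run config as JSON and return its hash
#'
#' The hash covers the analysis settings only (not the output path), so two
#' runs with identical settings stamp identical hashes wherever they write.
#'
#' @param config A [run_config()].
#' @param path Output JSON path; defaults to `config.json` in the run's
#'   output directory.
#' @return The MD5 hash of the canonical settings.
#' @export
write_run_config <- function(config,
                             path = file.path(config$out_dir,
                                              "config.json")) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  settings <- unclass(config)
  settings$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(settings, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Read a run config back from JSON
#' @param path JSON path written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[setdiff(names(x), character(0))])
}
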