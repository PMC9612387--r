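#' Names and class partition of the 93-feature profile
#'
#' @return Named character vector: names are the 93 feature names, values
#'   the feature class (`firstorder`, `glcm`, `glrlm`, `glszm`, `gldm`,
#'   `ngtdm`). The partition is 18 + 24 + 16 + 16 + 14 + 5.
#' @export
feature_classes <- function() {
  toy <- array(c(1, 2, 3, 4, 2, 3, 1, 4), dim = c(2, 2, 2))
  msk <- array(TRUE, dim = c(2, 2, 2))
  v <- extract_all(toy, msk)
  stats::setNames(sub("_.*$", "", names(v)), names(v))
}

#' Extract the full 93-feature radiomic profile from a VOI
#'
#' Concatenates the 18 first-order features and the 75 texture features
#' (GLCM 24, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5) computed on the original
#' image restricted to the mask -- no resampling or filtering. Feature
#' names are prefixed with their class (`firstorder_Mean`, `glcm_Idmn`,
#' ...).
#'
#' @param image 3D numeric array (typically a [parametric_image()]'s
#'   `voxels`).
#' @param mask Logical 3D array with >= 2 voxels.
#' @param config A [discretization_config()].
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @return Named numeric vector of exactly 93 finite values with attribute
#'   `degenerate` (names of features computed under a degenerate-input
#'   convention).
#' @export
extract_all <- function(image, mask, config = discretization_config(),
                        voxel_size_mm = c(1, 1, 1)) {
  if (inherits(image, "parametric_image")) {
    voxel_size_mm <- image$voxel_size_mm
    image <- image$voxels
  }
  fo <- first_order_features(image, mask, config, voxel_size_mm)
  tx <- texture_features(image, mask, config)
  out <- c(fo, tx)
  stopifnot(length(out) == 93L)
  if (!all(is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite features: ", paste(bad, collapse = ", "))
  }
  attr(out, "degenerate") <- c(attr(fo, "degenerate"),
                               attr(tx, "degenerate"))
  out
}

#' Cohort-level feature table
#'
#' Runs the parametric-map and feature-extraction stages for every patient
#' of a cohort: three parametric images (TBR 5-15, TBR 20-40, TTP) times two
#' VOIs (tumor, mirrored background) times 93 features. Patients may be
#' supplied as a list of `synthetic_patient` objects or generated one at a
#' time from a [cohort_plan()] (memory-friendly for large grids).
#'
#' @param patients List of `synthetic_patient`, or `NULL` to generate from
#'   `plan`.
#' @param plan A [cohort_plan()] (required when `patients` is `NULL`; used
#'   for phenotype annotation otherwise when attached as attribute).
#' @param spec,schedule Passed to [simulate_patient()] when generating.
#' @param config A [discretization_config()].
#' @param smoothing_window Passed to [ttp_map()].
#' @return Data frame (class `feature_table`) with identifier columns
#'   `patient_id`, `phenotype`, `voi_label`, `image_kind`, a
#'   `n_degenerate` count, and the 93 feature columns.
#' @export
extract_cohort <- function(patients = NULL, plan = NULL,
                           spec = phantom_spec(),
                           schedule = default_frame_schedule(),
                           config = discretization_config(),
                           smoothing_window = NULL) {
  if (is.null(patients) && is.null(plan)) {
    stop("supply patients or a cohort plan")
  }
  if (is.null(plan)) plan <- attr(patients, "plan")
  n <- if (is.null(patients)) nrow(plan) else length(patients)
  rows <- vector("list", n * 6L)
  ri <- 0L
  for (i in seq_len(n)) {
    pt <- if (is.null(patients)) {
      simulate_patient(spec, plan_tissue_params(plan, i), schedule,
                       seed = plan$seed[i])
    } else {
      patients[[i]]
    }
    pid <- if (!is.null(plan)) plan$patient_id[i] else sprintf("P%03d", i)
    phen <- if (!is.null(plan)) plan$phenotype[i] else pt$truth$tumor$phenotype
    maps <- parametric_maps(pt$dynamic_image, pt$voi_set$crescent_mask,
                            smoothing_window)
    for (kind in image_kinds()) {
      for (voi in c("tumor", "mirrored")) {
        msk <- if (voi == "tumor") pt$voi_set$tumor_mask else
          pt$voi_set$mirrored_mask
        fv <- extract_all(maps[[kind]], msk, config)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          patient_id = pid, phenotype = phen, voi_label = voi,
          image_kind = kind,
          n_degenerate = length(attr(fv, "degenerate")),
          t(fv), check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", class(out))
  out
}

#' Feature columns of a feature table
#' @param table A `feature_table` (or any data frame from
#'   [extract_cohort()]).
#' @return Character vector of the 93 feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("patient_id", "phenotype", "voi_label",
                          "image_kind", "n_degenerate"))
}

#' Voxel-wise local feature map
#'
#' Computes one named feature in a sliding cubic window around every in-mask
#' voxel (the window is intersected with the image bounds, so it shrinks at
#' the borders). Used for visualizing where in a lesion a texture feature
#' expresses, e.g. an Idmn homogeneity map over a TTP image.
#'
#' @param image 3D numeric array.
#' @param mask Logical 3D array; voxels outside get `NA`.
#' @param feature_name One of the 93 feature names.
#' @param window_voxels Odd cube edge length >= 3 (default 5).
#' @param config A [discretization_config()].
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @return 3D numeric array, `NA` outside the mask.
#' @export
feature_map <- function(image, mask, feature_name, window_voxels = 5L,
                        config = discretization_config(),
                        voxel_size_mm = c(1, 1, 1)) {
  window_voxels <- as.integer(window_voxels)
  if (window_voxels < 3L || window_voxels %% 2L == 0L) {
    stop("window_voxels must be an odd integer >= 3")
  }
  known <- names(extract_all(array(c(1, 2, 3, 4, 2, 3, 1, 4),
                                   dim = c(2, 2, 2)),
                             array(TRUE, dim = c(2, 2, 2))))
  if (!feature_name %in% known) stop("unknown feature: ", feature_name)
  mask <- mask > 0
  dm <- dim(image)
  h <- (window_voxels - 1L) %/% 2L
  out <- array(NA_real_, dim = dm)
  for (v in seq_len(prod(dm))[as.vector(mask)]) {
    ijk <- arrayInd(v, dm)
    xs <- max(1L, ijk[1] - h):min(dm[1], ijk[1] + h)
    ys <- max(1L, ijk[2] - h):min(dm[2], ijk[2] + h)
    zs <- max(1L, ijk[3] - h):min(dm[3], ijk[3] + h)
    sub <- image[xs, ys, zs, drop = FALSE]
    sub <- array(sub, dim = c(length(xs), length(ys), length(zs)))
    fv <- extract_all(sub, array(TRUE, dim = dim(sub)), config,
                      voxel_size_mm)
    out[v] <- fv[[feature_name]]
  }
  out
}
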