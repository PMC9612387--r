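#' Ellipsoidal binary mask
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param center Numeric length-3 center in (1-based) voxel coordinates.
#' @param radii Numeric length-3 semi-axes in voxels.
#' @return Logical 3D array.
#' @export
ellipsoid_mask <- function(grid_shape, center, radii) {
  stopifnot(length(grid_shape) == 3L, length(center) == 3L,
            length(radii) == 3L, all(radii > 0))
  ax <- (seq_len(grid_shape[1]) - center[1]) / radii[1]
  ay <- (seq_len(grid_shape[2]) - center[2]) / radii[2]
  az <- (seq_len(grid_shape[3]) - center[3]) / radii[3]
  d2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  array(d2 <= 1, dim = grid_shape)
}

#' Specification of the digital brain phantom
#'
#' Defines the geometry and noise level of one synthetic patient: a
#' left-right symmetric grid with an ellipsoidal tumor strictly on one side
#' of the midsagittal plane, a ventricle ellipsoid straddling the midline,
#' and a crescent-shaped background region in the hemisphere contralateral
#' to the tumor (a spherical shell sector, minus ventricle and mirrored
#' tumor so it samples pure healthy tissue). Defaults: 64 x 64 x 48 grid at
#' 3 mm isotropic resolution with ~15 mm tumor semi-axes -- small enough for
#' desk-scale analysis while keeping realistic VOI voxel counts.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param voxel_size_mm Numeric length-3 voxel size in mm.
#' @param midsagittal_index Left-right symmetry plane along axis 1; defaults
#'   to the grid center `(grid_shape[1] + 1) / 2`.
#' @param tumor_center,tumor_radii_mm Ellipsoid center (voxels) and
#'   semi-axes (mm) of the tumor, strictly on one side of the midplane.
#' @param ventricle_center,ventricle_radii_mm Ventricle ellipsoid near the
#'   midline.
#' @param crescent_radii_mm Inner/outer radii (mm) of the spherical shell
#'   whose contralateral sector forms the crescent background VOI.
#' @param noise_scale Multiplier of the frame noise standard deviation
#'   `sqrt(activity / frame duration)`; 0 gives noise-free data.
#' @param seed Integer seed stored with the spec (used by
#'   [simulate_patient()] when no explicit seed is given).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         voxel_size_mm = c(3, 3, 3),
                         midsagittal_index = (grid_shape[1] + 1) / 2,
                         tumor_center = NULL,
                         tumor_radii_mm = c(15, 15, 15),
                         ventricle_center = NULL,
                         ventricle_radii_mm = c(13, 25, 19),
                         crescent_radii_mm = c(27, 39),
                         noise_scale = 1,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            all(voxel_size_mm > 0), noise_scale >= 0,
            length(crescent_radii_mm) == 2L,
            crescent_radii_mm[1] < crescent_radii_mm[2])
  cy <- round(grid_shape[2] / 2); cz <- round(grid_shape[3] / 2)
  if (is.null(tumor_center)) {
    tumor_center <- c(round(grid_shape[1] * 0.75), cy, cz)
  }
  if (is.null(ventricle_center)) {
    ventricle_center <- c(round(midsagittal_index - 0.1 * grid_shape[1]),
                          cy + 2, cz)
  }
  spec <- structure(
    list(grid_shape = grid_shape, voxel_size_mm = as.numeric(voxel_size_mm),
         midsagittal_index = midsagittal_index,
         tumor_center = tumor_center, tumor_radii_mm = tumor_radii_mm,
         ventricle_center = ventricle_center,
         ventricle_radii_mm = ventricle_radii_mm,
         crescent_radii_mm = crescent_radii_mm,
         noise_scale = noise_scale, seed = as.integer(seed)),
    class = "phantom_spec")
  .check_phantom_spec(spec)
  spec
}

.mm_to_vox <- function(radii_mm, voxel_size_mm) {
  pmax(radii_mm / voxel_size_mm, 1e-6)
}

# Build all masks of a phantom spec; validates geometric invariants.
.phantom_masks <- function(spec) {
  gs <- spec$grid_shape
  tumor <- ellipsoid_mask(gs, spec$tumor_center,
                          .mm_to_vox(spec$tumor_radii_mm, spec$voxel_size_mm))
  ventricle <- ellipsoid_mask(gs, spec$ventricle_center,
                              .mm_to_vox(spec$ventricle_radii_mm,
                                         spec$voxel_size_mm))
  if (any(tumor & ventricle)) stop("tumor and ventricle regions overlap")
  mirrored <- mirror_mask(tumor, spec$midsagittal_index, ventricle)

  # crescent: contralateral sector of a spherical shell centered mid-brain
  ctr <- c(spec$midsagittal_index, (gs[2] + 1) / 2, (gs[3] + 1) / 2)
  rv_in <- .mm_to_vox(rep(spec$crescent_radii_mm[1], 3), spec$voxel_size_mm)
  rv_out <- .mm_to_vox(rep(spec$crescent_radii_mm[2], 3), spec$voxel_size_mm)
  shell <- ellipsoid_mask(gs, ctr, rv_out) & !ellipsoid_mask(gs, ctr, rv_in)
  tumor_side <- sign(spec$tumor_center[1] - spec$midsagittal_index)
  xcontra <- if (tumor_side > 0) {
    seq_len(gs[1]) < spec$midsagittal_index
  } else {
    seq_len(gs[1]) > spec$midsagittal_index
  }
  contra <- array(rep(xcontra, times = gs[2] * gs[3]), dim = gs)
  crescent <- shell & contra & !ventricle & !mirrored
  if (!sum(crescent)) stop("crescent region is empty; enlarge the grid or shell")
  list(tumor = tumor, ventricle = ventricle, mirrored = mirrored,
       crescent = crescent)
}

.check_phantom_spec <- function(spec) {
  gs <- spec$grid_shape
  if (any(spec$tumor_center < 1) || any(spec$tumor_center > gs)) {
    stop("tumor center outside the grid")
  }
  rv <- .mm_to_vox(spec$tumor_radii_mm, spec$voxel_size_mm)
  side <- spec$tumor_center[1] - spec$midsagittal_index
  if (abs(side) <= rv[1]) stop("tumor intersects the midsagittal plane")
  invisible(.phantom_masks(spec))
}

#' Default per-region kinetic parameters
#'
#' @param tumor_phenotype `"isometabolic"` or `"photopenic"`.
#' @return Named list of [kinetic_params()] for `background`, `tumor`,
#'   `ventricle`.
#' @export
default_tissue_params <- function(tumor_phenotype = c("isometabolic",
                                                      "photopenic")) {
  tumor_phenotype <- match.arg(tumor_phenotype)
  list(background = kinetic_params("background"),
       tumor = kinetic_params(tumor_phenotype),
       ventricle = kinetic_params("ventricle"))
}

#' Simulate one synthetic dynamic-PET patient
#'
#' Every voxel's frame value is the duration-weighted mean of its region's
#' noiseless time-activity curve over that frame, plus zero-mean Gaussian
#' noise with standard deviation `noise_scale * sqrt(level / duration_s)` --
#' a count-statistics approximation for reconstructed frames (short early
#' frames are noisy, long late frames quiet). Tumor voxels follow the tumor
#' kinetics, ventricle voxels the low-uptake ventricle curve, everything
#' else the healthy background.
#'
#' @param spec A [phantom_spec()].
#' @param tissue_params Named list of [kinetic_params()] with entries
#'   `background`, `tumor`, `ventricle` (see [default_tissue_params()]).
#' @param schedule A [frame_schedule()].
#' @param seed Integer seed; defaults to `spec$seed`. Identical
#'   `(spec, tissue_params, seed)` reproduce bit-identical data.
#' @return An object of class `synthetic_patient`: list with
#'   `dynamic_image`, `voi_set`, `truth` (the tissue params) and `seed`.
#' @export
simulate_patient <- function(spec,
                             tissue_params = default_tissue_params(),
                             schedule = default_frame_schedule(),
                             seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!all(c("background", "tumor", "ventricle") %in% names(tissue_params))) {
    stop("tissue_params needs entries background, tumor, ventricle")
  }
  masks <- .phantom_masks(spec)
  gs <- spec$grid_shape
  nvox <- prod(gs)
  nfr <- length(schedule)

  curves <- rbind(
    background = frame_activity(tissue_params$background, schedule),
    tumor      = frame_activity(tissue_params$tumor, schedule),
    ventricle  = frame_activity(tissue_params$ventricle, schedule)
  )
  region <- rep(1L, nvox)                 # background
  region[which(masks$tumor)] <- 2L
  region[which(masks$ventricle)] <- 3L

  vox <- array(0, dim = c(gs, nfr))
  durs <- schedule$frame_durations_s
  old_seed <- NULL
  set.seed(as.integer(seed))
  for (f in seq_len(nfr)) {
    level <- curves[region, f]
    if (spec$noise_scale > 0) {
      sd_f <- spec$noise_scale * sqrt(pmax(level, 0) / durs[f])
      level <- level + stats::rnorm(nvox, 0, sd_f)
    }
    vox[, , , f] <- level
  }
  vs <- voi_set(masks$tumor, masks$mirrored, masks$crescent, masks$ventricle,
                spec$midsagittal_index)
  structure(
    list(dynamic_image = dynamic_image(vox, schedule, spec$voxel_size_mm),
         voi_set = vs, truth = tissue_params, seed = as.integer(seed),
         spec = spec),
    class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("synthetic_patient (seed %d): tumor phenotype %s\n",
              x$seed, x$truth$tumor$phenotype))
  print(x$dynamic_image)
  print(x$voi_set)
  invisible(x)
}

#' Plan a synthetic cohort
#'
#' Draws per-patient seeds and jittered kinetic parameters for a cohort with
#' a given isometabolic/photopenic phenotype mix. Phenotype counts are the
#' largest-remainder rounding of `n_patients * phenotype_mix`. All draws
#' derive deterministically from `base_seed`, so two plans with the same
#' arguments are identical.
#'
#' The default jitter emulates between-patient variability: log-normal
#' amplitude spread (10%), background perfusion peak 4 +/- 0.5 min, tumor
#' peak time uniform in 33-39 min p.i. (ascending kinetics), isometabolic
#' late level within 2% of background (visually FET-negative), photopenic
#' late level 0.75 +/- 0.07 (clamped to 0.55-0.92).
#'
#' @param n_patients Number of patients (>= 1).
#' @param phenotype_mix Length-2 fractions `c(isometabolic, photopenic)`
#'   summing to 1.
#' @param base_seed Integer master seed.
#' @param jitter Named list overriding any of the spread settings
#'   `amplitude_sdlog`, `bg_peak_mean`, `bg_peak_sd`, `tumor_peak_range`,
#'   `iso_late_sd`, `photo_late_mean`, `photo_late_sd`.
#' @return Data frame (class `cohort_plan`) with one row per patient:
#'   `patient_id`, `phenotype`, `seed`, `amplitude`, `bg_peak_min`,
#'   `tumor_peak_min`, `tumor_late_level`.
#' @export
cohort_plan <- function(n_patients,
                        phenotype_mix = c(isometabolic = 29 / 46,
                                          photopenic = 17 / 46),
                        base_seed = 1L,
                        jitter = list()) {
  stopifnot(n_patients >= 1)
  phenotype_mix <- as.numeric(phenotype_mix)
  if (length(phenotype_mix) != 2L || any(phenotype_mix < 0) ||
      abs(sum(phenotype_mix) - 1) > 1e-8) {
    stop("phenotype_mix must be two non-negative fractions summing to 1")
  }
  j <- utils::modifyList(
    list(amplitude_sdlog = 0.1, bg_peak_mean = 4, bg_peak_sd = 0.5,
         tumor_peak_range = c(33, 39), iso_late_sd = 0.02,
         photo_late_mean = 0.75, photo_late_sd = 0.07),
    jitter)
  raw <- n_patients * phenotype_mix
  n_iso <- floor(raw[1])
  n_photo <- floor(raw[2])
  rem <- n_patients - n_iso - n_photo
  if (rem > 0) {  # largest remainder
    ord <- order(raw - floor(raw), decreasing = TRUE)
    for (k in seq_len(rem)) {
      if (ord[(k - 1) %% 2 + 1] == 1) n_iso <- n_iso + 1 else
        n_photo <- n_photo + 1
    }
  }
  phen <- c(rep("isometabolic", n_iso), rep("photopenic", n_photo))
  set.seed(as.integer(base_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
  amp <- exp(stats::rnorm(n_patients, 0, j$amplitude_sdlog))
  bgp <- pmin(pmax(stats::rnorm(n_patients, j$bg_peak_mean, j$bg_peak_sd),
                   2.5), 6)
  tp <- stats::runif(n_patients, j$tumor_peak_range[1], j$tumor_peak_range[2])
  ll <- ifelse(
    phen == "isometabolic",
    pmin(pmax(stats::rnorm(n_patients, 1, j$iso_late_sd), 0.96), 1.04),
    pmin(pmax(stats::rnorm(n_patients, j$photo_late_mean, j$photo_late_sd),
              0.55), 0.92))
  plan <- data.frame(patient_id = sprintf("P%03d", seq_len(n_patients)),
                     phenotype = phen, seed = seeds, amplitude = amp,
                     bg_peak_min = bgp, tumor_peak_min = tp,
                     tumor_late_level = ll, stringsAsFactors = FALSE)
  class(plan) <- c("cohort_plan", class(plan))
  plan
}

#' Tissue parameters for one planned patient
#' @param plan A [cohort_plan()].
#' @param i Row index.
#' @return Named list of [kinetic_params()] as taken by [simulate_patient()].
#' @export
plan_tissue_params <- function(plan, i) {
  r <- plan[i, ]
  list(
    background = kinetic_params("background", amplitude = r$amplitude,
                                peak_time_min = r$bg_peak_min),
    tumor = kinetic_params(r$phenotype, amplitude = r$amplitude,
                           peak_time_min = r$tumor_peak_min,
                           late_level = r$tumor_late_level),
    ventricle = kinetic_params("ventricle", amplitude = r$amplitude)
  )
}

#' Simulate a synthetic cohort
#'
#' Materializes every patient of a [cohort_plan()]. For large grids consider
#' iterating over the plan with [simulate_patient()] and processing patients
#' one at a time instead of holding the whole cohort in memory.
#'
#' @inheritParams cohort_plan
#' @param spec A [phantom_spec()] shared by all patients.
#' @param schedule A [frame_schedule()].
#' @return List of `synthetic_patient`, named by patient id, with the plan
#'   attached as attribute `plan`.
#' @export
simulate_cohort <- function(n_patients,
                            phenotype_mix = c(isometabolic = 29 / 46,
                                              photopenic = 17 / 46),
                            base_seed = 1L,
                            spec = phantom_spec(),
                            schedule = default_frame_schedule(),
                            jitter = list()) {
  plan <- cohort_plan(n_patients, phenotype_mix, base_seed, jitter)
  patients <- lapply(seq_len(nrow(plan)), function(i) {
    simulate_patient(spec, plan_tissue_params(plan, i), schedule,
                     seed = plan$seed[i])
  })
  names(patients) <- plan$patient_id
  attr(patients, "plan") <- plan
  patients
}
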