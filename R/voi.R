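#' Volumes of interest for one patient
#'
#' Bundles the four binary masks the analysis uses: the tumor VOI, the tumor
#' VOI mirrored into the contralateral hemisphere (ventricle excluded), the
#' crescent-shaped normalization background, and the ventricle mask used for
#' exclusion. All masks are logical 3D arrays on a common grid. Voxel
#' indices are 1-based (R convention); the midsagittal plane may sit on a
#' voxel column (integer index) or between two columns (half-integer).
#'
#' @param tumor_mask,mirrored_mask,crescent_mask,ventricle_mask Logical 3D
#'   arrays of identical dimension.
#' @param midsagittal_index Position of the left-right symmetry plane along
#'   the first array axis; integer or half-integer.
#' @return An object of class `voi_set`.
#' @export
voi_set <- function(tumor_mask, mirrored_mask, crescent_mask, ventricle_mask,
                    midsagittal_index) {
  masks <- list(tumor_mask = tumor_mask, mirrored_mask = mirrored_mask,
                crescent_mask = crescent_mask, ventricle_mask = ventricle_mask)
  masks <- lapply(masks, function(m) {
    if (!is.array(m) || length(dim(m)) != 3L) stop("masks must be 3D arrays")
    array(m > 0, dim = dim(m))
  })
  dims <- vapply(masks, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L) stop("all masks must share one grid")
  structure(c(masks, list(midsagittal_index = midsagittal_index)),
            class = "voi_set")
}

#' @export
print.voi_set <- function(x, ...) {
  cat(sprintf(
    "voi_set on %s grid: tumor %d, mirrored %d, crescent %d, ventricle %d voxels\n",
    paste(dim(x$tumor_mask), collapse = "x"),
    sum(x$tumor_mask), sum(x$mirrored_mask),
    sum(x$crescent_mask), sum(x$ventricle_mask)))
  invisible(x)
}

#' Mirror a tumor mask across the midsagittal plane
#'
#' Reflects a binary mask about the left-right symmetry plane of the grid
#' (index flip along the first axis: `x -> 2 * midsagittal_index - x`) and
#' removes voxels of the exclusion mask (typically the ventricle). This
#' yields the contralateral healthy-tissue VOI with identical shape used as
#' the paired background sample for radiomics. The reflection is a pure
#' index flip: it assumes the grid is already aligned with its symmetry
#' plane, as synthetic phantoms are.
#'
#' @param tumor_mask Logical 3D array, entirely on one side of the plane.
#' @param midsagittal_index Plane position along axis 1 (integer or
#'   half-integer; `2 * midsagittal_index` must be a whole number so the
#'   reflection maps voxels onto voxels).
#' @param exclusion_mask Optional logical 3D array; reflected voxels falling
#'   inside it are dropped.
#' @return Logical 3D mask with attribute `excluded_count`, the number of
#'   reflected voxels removed by the exclusion mask.
#' @export
mirror_mask <- function(tumor_mask, midsagittal_index, exclusion_mask = NULL) {
  if (!is.array(tumor_mask) || length(dim(tumor_mask)) != 3L) {
    stop("tumor_mask must be a 3D array")
  }
  tumor_mask <- tumor_mask > 0
  if (!sum(tumor_mask)) stop("tumor mask is empty")
  two_p <- 2 * midsagittal_index
  if (abs(two_p - round(two_p)) > 1e-9) {
    stop("2 * midsagittal_index must be a whole number")
  }
  idx <- which(tumor_mask, arr.ind = TRUE)
  x <- idx[, 1]
  if (any(x == midsagittal_index) ||
      (min(x) < midsagittal_index && max(x) > midsagittal_index)) {
    stop("tumor mask touches or crosses the midsagittal plane")
  }
  xr <- round(two_p) - x
  if (any(xr < 1) || any(xr > dim(tumor_mask)[1])) {
    stop("reflected mask falls outside the grid")
  }
  out <- array(FALSE, dim = dim(tumor_mask))
  out[cbind(xr, idx[, 2], idx[, 3])] <- TRUE
  excluded <- 0L
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(tumor_mask))) {
      stop("exclusion mask must be on the same grid")
    }
    drop <- out & (exclusion_mask > 0)
    excluded <- sum(drop)
    out <- out & !drop
  }
  if (!sum(out)) stop("mirrored mask is empty after exclusion")
  attr(out, "excluded_count") <- excluded
  out
}

#' Validate a VOI set against its structural invariants
#'
#' Checks that tumor and mirrored masks are disjoint, that the mirrored mask
#' shares no voxel with the ventricle, and that all masks are non-empty.
#' This is a reporting operation: it never throws.
#'
#' @param vs A [voi_set()].
#' @return List with `valid` (logical) and `violations` (character vector,
#'   empty when valid).
#' @export
validate_voi_set <- function(vs) {
  stopifnot(inherits(vs, "voi_set"))
  v <- character(0)
  if (any(vs$tumor_mask & vs$mirrored_mask)) {
    v <- c(v, "tumor and mirrored masks overlap")
  }
  if (any(vs$mirrored_mask & vs$ventricle_mask)) {
    v <- c(v, "mirrored mask overlaps ventricle mask")
  }
  for (nm in c("tumor_mask", "mirrored_mask", "crescent_mask",
               "ventricle_mask")) {
    if (!sum(vs[[nm]])) v <- c(v, paste(nm, "is empty"))
  }
  list(valid = length(v) == 0L, violations = v)
}
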