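#' 4D dynamic PET image
#'
#' @param voxels 4D numeric array `(x, y, z, frame)` of activity values
#'   (arbitrary units); frame axis last.
#' @param schedule A [frame_schedule()] whose length matches the frame axis.
#' @param voxel_size_mm Numeric length-3 voxel size in mm.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(voxels, schedule, voxel_size_mm = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L) {
    stop("voxels must be a 4D array (x, y, z, frame)")
  }
  stopifnot(inherits(schedule, "frame_schedule"))
  if (dim(voxels)[4] != length(schedule)) {
    stop(sprintf("frame axis (%d) does not match schedule length (%d)",
                 dim(voxels)[4], length(schedule)))
  }
  if (!all(is.finite(voxels))) stop("activity values must be finite")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  structure(list(voxels = voxels, schedule = schedule,
                 voxel_size_mm = voxel_size_mm),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "dynamic_image: %dx%dx%d voxels (%.3g mm), %d frames, 0-%.4g min p.i.\n",
    d[1], d[2], d[3], prod(x$voxel_size_mm)^(1 / 3), d[4],
    schedule_end(x$schedule) / 60))
  invisible(x)
}

#' 3D parametric image (TBR or TTP)
#'
#' @param voxels 3D numeric array.
#' @param kind One of `"TBR_5_15"`, `"TBR_20_40"`, `"TTP"`.
#' @param voxel_size_mm Numeric length-3 voxel size in mm.
#' @return An object of class `parametric_image`; `units` is
#'   `"ratio"` for TBR kinds and `"min"` for TTP.
#' @export
parametric_image <- function(voxels, kind = c("TBR_5_15", "TBR_20_40", "TTP"),
                             voxel_size_mm = c(1, 1, 1)) {
  kind <- match.arg(kind)
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("voxels must be a 3D array")
  }
  if (startsWith(kind, "TBR") && any(voxels < 0, na.rm = TRUE)) {
    stop("TBR voxels must be non-negative")
  }
  structure(list(voxels = voxels, kind = kind,
                 units = if (kind == "TTP") "min" else "ratio",
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "parametric_image")
}

#' @export
print.parametric_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("parametric_image [%s, %s]: %dx%dx%d, range %.4g-%.4g\n",
              x$kind, x$units, d[1], d[2], d[3],
              min(x$voxels, na.rm = TRUE), max(x$voxels, na.rm = TRUE)))
  invisible(x)
}

#' Image kinds produced by the pipeline
#' @return Character vector of the three parametric image kinds.
#' @export
image_kinds <- function() c("TBR_5_15", "TBR_20_40", "TTP")
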