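#' Duration-weighted summation image over a time window
#'
#' Selects all frames whose mid-time lies in `[t_start, t_end)` minutes and
#' returns their duration-weighted mean image. Using the weighted mean
#' rather than the raw sum makes the result independent of frame binning;
#' for the tumor-to-background ratio the two are equivalent anyway.
#'
#' @param dynamic A [dynamic_image()].
#' @param window Numeric length-2 `c(t_start, t_end)` in minutes p.i.
#' @return 3D numeric array with attribute `frames` (selected frame
#'   indices).
#' @export
sum_frames <- function(dynamic, window) {
  stopifnot(inherits(dynamic, "dynamic_image"), length(window) == 2L,
            window[1] < window[2])
  mid <- frame_mid_times(dynamic$schedule)
  sel <- which(mid >= window[1] & mid < window[2])
  if (!length(sel)) {
    stop(sprintf("no frame mid-time falls in [%.4g, %.4g) min",
                 window[1], window[2]))
  }
  w <- dynamic$schedule$frame_durations_s[sel]
  w <- w / sum(w)
  d <- dim(dynamic$voxels)
  out <- array(0, dim = d[1:3])
  for (k in seq_along(sel)) {
    out <- out + w[k] * dynamic$voxels[, , , sel[k]]
  }
  attr(out, "frames") <- sel
  out
}

#' Normalize a static image to the crescent background mean
#'
#' Divides a static summation image voxel-wise by the mean value inside the
#' crescent-shaped background VOI of the same image, yielding a
#' tumor-to-background ratio (TBR) image.
#'
#' @param static_image 3D numeric array (e.g. from [sum_frames()]).
#' @param crescent_mask Logical 3D mask of the normalization region.
#' @param kind `"TBR_5_15"` or `"TBR_20_40"`.
#' @param voxel_size_mm Voxel size carried into the output.
#' @return A [parametric_image()] of the requested TBR kind with attribute
#'   `background_mean`.
#' @export
tbr_normalize <- function(static_image, crescent_mask,
                          kind = c("TBR_20_40", "TBR_5_15"),
                          voxel_size_mm = c(1, 1, 1)) {
  kind <- match.arg(kind)
  stopifnot(identical(dim(static_image), dim(crescent_mask)))
  bg <- mean(static_image[crescent_mask > 0])
  if (!is.finite(bg) || bg <= 0) {
    stop("crescent background mean must be finite and > 0")
  }
  out <- parametric_image(pmax(static_image / bg, 0), kind, voxel_size_mm)
  attr(out, "background_mean") <- bg
  out
}

#' Voxel-wise time-to-peak map
#'
#' For each voxel, optionally smooths the time-activity curve with a
#' centered moving average over `smoothing_window` frames (the window
#' shrinks symmetrically at the acquisition edges), then reports the
#' mid-time in minutes of the first frame attaining the curve maximum.
#' Ascending kinetics therefore map to the final frame mid-time (34.67 min
#' for the standard 16-frame schedule); no sub-frame interpolation is
#' performed, so TTP values always belong to the set of frame mid-times.
#'
#' @param dynamic A [dynamic_image()] with at least 3 frames.
#' @param smoothing_window `NULL` (default, no smoothing) or an odd integer
#'   number of frames.
#' @return A [parametric_image()] of kind `"TTP"`.
#' @export
ttp_map <- function(dynamic, smoothing_window = NULL) {
  stopifnot(inherits(dynamic, "dynamic_image"))
  d <- dim(dynamic$voxels)
  nfr <- d[4]
  if (nfr < 3L) stop("TTP needs at least 3 frames")
  tac <- matrix(dynamic$voxels, nrow = prod(d[1:3]), ncol = nfr)
  if (!is.null(smoothing_window)) {
    k <- as.integer(smoothing_window)
    if (k < 1L || k %% 2L == 0L) stop("smoothing_window must be odd")
    if (k > 1L) {
      half <- (k - 1L) %/% 2L
      sm <- matrix(0, nrow = nrow(tac), ncol = nfr)
      for (f in seq_len(nfr)) {
        h <- min(half, f - 1L, nfr - f)   # shrink at the edges
        sm[, f] <- rowMeans(tac[, (f - h):(f + h), drop = FALSE])
      }
      tac <- sm
    }
  }
  peak <- max.col(tac, ties.method = "first")
  mid <- frame_mid_times(dynamic$schedule)
  parametric_image(array(mid[peak], dim = d[1:3]), "TTP",
                   dynamic$voxel_size_mm)
}

#' All three parametric maps of one patient
#'
#' Convenience wrapper producing the early TBR (5-15 min), standard TBR
#' (20-40 min) and TTP images from a dynamic image and its crescent mask.
#'
#' @param dynamic A [dynamic_image()].
#' @param crescent_mask Logical 3D normalization mask.
#' @param smoothing_window Passed to [ttp_map()].
#' @return Named list of [parametric_image()] (`TBR_5_15`, `TBR_20_40`,
#'   `TTP`).
#' @export
parametric_maps <- function(dynamic, crescent_mask, smoothing_window = NULL) {
  list(
    TBR_5_15 = tbr_normalize(sum_frames(dynamic, c(5, 15)), crescent_mask,
                             "TBR_5_15", dynamic$voxel_size_mm),
    TBR_20_40 = tbr_normalize(sum_frames(dynamic, c(20, 40)), crescent_mask,
                              "TBR_20_40", dynamic$voxel_size_mm),
    TTP = ttp_map(dynamic, smoothing_window)
  )
}
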