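#' Gray-level discretization settings
#'
#' Texture features operate on integer gray levels. Two modes are
#' supported: `fixed_bin_count` (default, 32 bins spanning the in-mask
#' intensity range -- appropriate for ratio-scaled TBR images and the small
#' discrete value set of TTP maps) and `fixed_bin_width` (levels
#' `floor((x - min) / bin_width) + 1`).
#'
#' @param mode `"fixed_bin_count"` or `"fixed_bin_width"`.
#' @param bin_count Integer >= 2 (count mode).
#' @param bin_width Positive intensity width (width mode).
#' @return An object of class `discretization_config`.
#' @export
discretization_config <- function(mode = c("fixed_bin_count",
                                           "fixed_bin_width"),
                                  bin_count = 32L, bin_width = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed_bin_count") {
    bin_count <- as.integer(bin_count)
    if (is.na(bin_count) || bin_count < 2L) stop("bin_count must be >= 2")
  } else {
    if (is.null(bin_width) || !is.finite(bin_width) || bin_width <= 0) {
      stop("bin_width must be > 0 in fixed_bin_width mode")
    }
  }
  structure(list(mode = mode, bin_count = bin_count, bin_width = bin_width),
            class = "discretization_config")
}

#' Discretize in-mask intensities to integer gray levels
#'
#' Count mode maps the in-mask range `[min, max]` onto levels
#' `1..bin_count` (`floor(bin_count * (x - min) / range) + 1`, with the
#' maximum clamped into the top bin); width mode uses
#' `floor((x - min) / bin_width) + 1`. A constant region yields a single
#' level 1 and is flagged degenerate rather than treated as an error.
#'
#' @param image 3D numeric array.
#' @param mask Logical 3D array, non-empty, same grid.
#' @param config A [discretization_config()].
#' @return Integer 3D array with `NA` outside the mask; attributes
#'   `n_levels` (number of gray levels of the level scale) and `degenerate`
#'   (TRUE for a constant region in count mode).
#' @export
discretize <- function(image, mask, config = discretization_config()) {
  stopifnot(is.array(image), length(dim(image)) == 3L,
            identical(dim(image), dim(mask)),
            inherits(config, "discretization_config"))
  mask <- mask > 0
  if (!sum(mask)) stop("mask is empty")
  x <- image[mask]
  if (!all(is.finite(x))) stop("non-finite intensities inside the mask")
  degenerate <- FALSE
  if (config$mode == "fixed_bin_count") {
    rng <- max(x) - min(x)
    if (rng == 0) {
      lev <- rep(1L, length(x))
      degenerate <- TRUE
      n_levels <- 1L
    } else {
      lev <- pmin(floor(config$bin_count * (x - min(x)) / rng) + 1L,
                  config$bin_count)
      n_levels <- config$bin_count
    }
  } else {
    lev <- floor((x - min(x)) / config$bin_width) + 1L
    n_levels <- max(lev)
    degenerate <- n_levels == 1L
  }
  out <- array(NA_integer_, dim = dim(image))
  out[mask] <- as.integer(lev)
  attr(out, "n_levels") <- as.integer(n_levels)
  attr(out, "degenerate") <- degenerate
  out
}
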