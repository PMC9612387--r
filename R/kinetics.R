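#' Kinetic parameters of a synthetic time-activity curve
#'
#' Describes the noiseless time-activity curve (TAC) of one tissue class in
#' the synthetic phantom. Three phenotypes are distinguished:
#' `background` (healthy brain: early perfusion peak, stable plateau),
#' `isometabolic` (tumor indistinguishable from background in late static
#' images but with ascending kinetics, peak after 30 min p.i.) and
#' `photopenic` (uptake visibly below background). A fourth label,
#' `ventricle`, marks the low-uptake CSF compartment used for the
#' ventricle-exclusion mask.
#'
#' `late_level` is the target mean of the noiseless unit-amplitude curve over
#' the late 20-40 min window, expressed relative to a background curve of the
#' same amplitude (background has `late_level = 1` by definition); the
#' absolute late mean of the curve is `amplitude * late_level`.
#'
#' @param phenotype One of `"background"`, `"isometabolic"`, `"photopenic"`,
#'   `"ventricle"`.
#' @param amplitude Non-negative activity scale (arbitrary units).
#' @param peak_time_min Minutes p.i. at which the noiseless curve attains its
#'   maximum; must lie within the acquisition span.
#' @param late_level Ratio of the curve's 20-40 min mean to the background
#'   reference at equal amplitude. Must be positive; `> 30` min peaks with
#'   `late_level` near 1 define the isometabolic phenotype, `late_level < 1`
#'   the photopenic one.
#' @param plateau_tau_min Time constant (minutes) of the saturating uptake
#'   plateau.
#' @param bump_sigma_min Width (minutes) of the perfusion peak component.
#' @param bump_ratio Height of the perfusion peak relative to the plateau
#'   level.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(phenotype = c("background", "isometabolic",
                                         "photopenic", "ventricle"),
                           amplitude = 1,
                           peak_time_min = NULL,
                           late_level = NULL,
                           plateau_tau_min = 2,
                           bump_sigma_min = 2,
                           bump_ratio = 0.5) {
  phenotype <- match.arg(phenotype)
  defaults <- switch(phenotype,
    background   = list(peak_time_min = 4,  late_level = 1),
    isometabolic = list(peak_time_min = 36, late_level = 1),
    photopenic   = list(peak_time_min = 36, late_level = 0.75),
    ventricle    = list(peak_time_min = 3,  late_level = 0.3)
  )
  if (is.null(peak_time_min)) peak_time_min <- defaults$peak_time_min
  if (is.null(late_level)) late_level <- defaults$late_level
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("amplitude must be finite and >= 0")
  }
  if (!is.finite(late_level) || late_level <= 0) {
    stop("late_level must be finite and > 0")
  }
  if (phenotype == "isometabolic") {
    if (peak_time_min <= 30) {
      stop("isometabolic kinetics require peak_time_min > 30 min p.i.")
    }
    if (abs(late_level - 1) > 0.1) {
      stop("isometabolic kinetics require late_level within 10% of 1")
    }
  }
  if (phenotype == "photopenic" && late_level >= 1) {
    stop("photopenic kinetics require late_level < 1")
  }
  structure(
    list(phenotype = phenotype, amplitude = amplitude,
         peak_time_min = peak_time_min, late_level = late_level,
         plateau_tau_min = plateau_tau_min, bump_sigma_min = bump_sigma_min,
         bump_ratio = bump_ratio),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "kinetic_params: %s | amplitude %.3g, peak %.3g min, late level %.3g\n",
    x$phenotype, x$amplitude, x$peak_time_min, x$late_level))
  invisible(x)
}

# Solve the unit-amplitude TAC shape for a parameter set.
#
# shape(t) = L * (1 - exp(-t/tau)) + rho * L * exp(-(t - c)^2 / (2 sigma^2))
#
# L is solved linearly so that the mean of shape over the late window equals
# late_level; the bump center c is iterated so the dense-grid argmax lands on
# peak_time (the saturating plateau keeps rising slightly, which would push
# the maximum past the bump center if c were fixed at peak_time).
# Returns list(fun = function(t_min), argmax_min, L, c).
.tac_shape <- function(params, schedule) {
  t_end <- schedule_end(schedule) / 60
  tp <- params$peak_time_min
  if (!is.finite(tp) || tp < 0 || tp > t_end) {
    stop(sprintf("peak_time_min must lie within the acquisition span [0, %.4g] min",
                 t_end))
  }
  tau <- params$plateau_tau_min
  sigma <- params$bump_sigma_min
  rho <- params$bump_ratio
  grid <- seq(0, t_end, by = 1 / 120)  # 0.5 s grid
  win <- grid >= 20 & grid <= min(40, t_end)
  if (!any(win)) stop("acquisition does not cover the 20-40 min late window")
  plateau <- 1 - exp(-grid / tau)
  m_b <- mean(plateau[win])
  cc <- tp
  L <- NA_real_
  argmax <- NA_real_
  for (iter in 1:40) {
    bump <- exp(-((grid - cc)^2) / (2 * sigma^2))
    m_g <- mean(bump[win])
    L <- params$late_level / (m_b + rho * m_g)
    shape <- L * plateau + rho * L * bump
    argmax <- grid[which.max(shape)]
    if (abs(argmax - tp) <= 1 / 120) break
    cc <- cc + (tp - argmax)
  }
  force(L); force(cc)
  list(
    fun = function(t) {
      L * (1 - exp(-t / tau)) +
        rho * L * exp(-((t - cc)^2) / (2 * sigma^2))
    },
    argmax_min = argmax, L = L, c = cc
  )
}

#' Evaluate a noiseless synthetic time-activity curve
#'
#' The noiseless TAC is a saturating uptake plateau plus a localized
#' perfusion peak, calibrated so that (i) its maximum over a dense time grid
#' falls at `peak_time_min` and (ii) its mean over the late 20-40 min window
#' equals `amplitude * late_level` (background reference = `amplitude` at
#' `late_level` 1). This reproduces the qualitative FET kinetics the analysis
#' relies on: early-peaking healthy background, ascending late-peaking
#' isometabolic tumors, and globally reduced photopenic tumors.
#'
#' @param params A [kinetic_params()].
#' @param times_min Sorted ascending times (minutes p.i.) within the
#'   acquisition span.
#' @param schedule A [frame_schedule()]; defaults to
#'   [default_frame_schedule()].
#' @return Numeric vector of non-negative activity values, one per time.
#' @export
tac_model <- function(params, times_min, schedule = default_frame_schedule()) {
  stopifnot(inherits(params, "kinetic_params"))
  times_min <- as.numeric(times_min)
  if (is.unsorted(times_min)) stop("times_min must be sorted ascending")
  t_end <- schedule_end(schedule) / 60
  if (any(times_min < 0) || any(times_min > t_end + 1e-9)) {
    stop("times_min must lie within the acquisition span")
  }
  if (params$amplitude == 0) return(rep(0, length(times_min)))
  shape <- .tac_shape(params, schedule)
  params$amplitude * shape$fun(times_min)
}

#' Duration-weighted noiseless frame activities
#'
#' Integrates the noiseless TAC over each frame of the schedule and divides
#' by the frame duration, i.e. the frame values an ideal scanner would
#' report.
#'
#' @inheritParams tac_model
#' @return Numeric vector with one mean activity per frame.
#' @export
frame_activity <- function(params, schedule = default_frame_schedule()) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "frame_schedule"))
  if (params$amplitude == 0) return(rep(0, length(schedule)))
  shape <- .tac_shape(params, schedule)
  starts <- schedule$frame_starts_s / 60
  durs <- schedule$frame_durations_s / 60
  vapply(seq_along(starts), function(i) {
    tt <- seq(starts[i], starts[i] + durs[i], length.out = 61)
    v <- shape$fun(tt)
    # trapezoidal mean over the frame
    sum((v[-1] + v[-length(v)]) / 2 * diff(tt)) / durs[i]
  }, numeric(1)) * params$amplitude
}
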