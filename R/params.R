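#' Model parameters for the two-rule coiling simulator
#'
#' Bundles every tunable quantity of the kinematic model. The two behavioural
#' rules are (1) coiling starts around the contact point, and (2) once coiling
#' has started the tendril always attains a minimum coiling angle
#' (`theta_min`) over the stimulated contact window. A contact is maintained
#' through that curl if and only if the support surface is curved at least as
#' sharply as the curl the rule demands, i.e. `2 / diameter >=
#' theta_min_rad / contact_window`; otherwise the contact point lifts off and
#' is re-established closer to the tip. With the defaults the step-1
#' bifurcation diameter is `2 * contact_window / theta_min_rad` = 13.75 mm.
#'
#' @param theta_min Minimum coiling angle in degrees (> 0, <= 180). Default 25.
#' @param free_coil_diameter Intrinsic coil diameter (mm) the tendril relaxes
#'   to when coiling freely. Default 18.
#' @param coiling_rate Speed of curvature uptake in degrees per minute during
#'   the rapid coiling stage. Default 6 (a 25 degree curl completes in about
#'   4.2 min, inside the 5-minute window used to score the initial response).
#' @param contact_window Arc length (mm) of tendril around a contact point
#'   over which the minimum coiling angle is expressed. Default 3.
#' @param contact_tol Distance (mm) below which a tendril node and the support
#'   surface count as touching. Default 0.2.
#' @param stop_eps Per-frame angle change (degrees) below which motion counts
#'   as stopped, used when segmenting simulated series. Default 1.
#' @param root_contact_fraction Fraction of arc length from the root within
#'   which a secondary contact counts as "at the root" (clip-shape coiling).
#'   Default 0.25.
#' @param detach_wrap_threshold Total intrinsic wrap angle (degrees) required
#'   for coiling success. Default 360.
#' @param max_time Observation window in minutes. Default 180 (3 h).
#' @param dt Time step in minutes. Default 0.5.
#' @param ds Node spacing (mm) of the discretized tendril. Default 1.
#' @param jitter_sd Circumnutation proxy: standard deviation (mm) of the
#'   Gaussian sway displacing the root-side free segment each step. A sway
#'   exceeding the current clearance between the root quarter and the support
#'   (for `secondary_persistence` consecutive steps) creates the secondary
#'   root contact that starts clip-shape coiling. 0 (the default) gives a
#'   fully deterministic trial with no secondary contacts.
#' @param secondary_persistence Number of consecutive steps a root-side touch
#'   must persist before it counts as a secondary contact stimulus. Default 3.
#' @param detach_persistence Minutes without any contact after which a
#'   clip-shape trial detaches. Default 10.
#' @param seed Integer seed for the jitter random walk. Default 1.
#' @return An object of class `model_params` (a validated list).
#' @export
model_params <- function(theta_min = 25,
                         free_coil_diameter = 18,
                         coiling_rate = 6,
                         contact_window = 3,
                         contact_tol = 0.2,
                         stop_eps = 1,
                         root_contact_fraction = 0.25,
                         detach_wrap_threshold = 360,
                         max_time = 180,
                         dt = 0.5,
                         ds = 1,
                         jitter_sd = 0,
                         secondary_persistence = 3,
                         detach_persistence = 10,
                         seed = 1L) {
  p <- list(theta_min = theta_min, free_coil_diameter = free_coil_diameter,
            coiling_rate = coiling_rate, contact_window = contact_window,
            contact_tol = contact_tol, stop_eps = stop_eps,
            root_contact_fraction = root_contact_fraction,
            detach_wrap_threshold = detach_wrap_threshold,
            max_time = max_time, dt = dt, ds = ds, jitter_sd = jitter_sd,
            secondary_persistence = as.integer(secondary_persistence),
            detach_persistence = detach_persistence, seed = as.integer(seed))
  validate_model_params(p)
  class(p) <- "model_params"
  p
}

validate_model_params <- function(p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(p$theta_min) && p$theta_min > 0 && p$theta_min <= 180,
      "theta_min must be in (0, 180] degrees")
  chk(num1(p$free_coil_diameter) && p$free_coil_diameter > 0,
      "free_coil_diameter must be > 0 mm")
  chk(num1(p$coiling_rate) && p$coiling_rate > 0,
      "coiling_rate must be > 0 degrees/minute")
  chk(num1(p$contact_window) && p$contact_window > 0,
      "contact_window must be > 0 mm")
  chk(num1(p$contact_tol) && p$contact_tol > 0, "contact_tol must be > 0 mm")
  chk(num1(p$stop_eps) && p$stop_eps > 0, "stop_eps must be > 0 degrees")
  chk(num1(p$root_contact_fraction) && p$root_contact_fraction > 0 &&
        p$root_contact_fraction < 1,
      "root_contact_fraction must be in (0, 1)")
  chk(num1(p$detach_wrap_threshold) && p$detach_wrap_threshold > 0,
      "detach_wrap_threshold must be > 0 degrees")
  chk(num1(p$max_time) && p$max_time > 0, "max_time must be > 0 minutes")
  chk(num1(p$dt) && p$dt > 0, "dt must be > 0 minutes")
  chk(num1(p$ds) && p$ds > 0, "ds must be > 0 mm")
  chk(num1(p$jitter_sd) && p$jitter_sd >= 0, "jitter_sd must be >= 0 mm")
  chk(p$secondary_persistence >= 1L, "secondary_persistence must be >= 1 step")
  chk(num1(p$detach_persistence) && p$detach_persistence > 0,
      "detach_persistence must be > 0 minutes")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-rule coiling model parameters\n")
  cat(sprintf("  theta_min            %6.1f deg\n", x$theta_min))
  cat(sprintf("  free_coil_diameter   %6.1f mm\n", x$free_coil_diameter))
  cat(sprintf("  coiling_rate         %6.1f deg/min\n", x$coiling_rate))
  cat(sprintf("  contact_window       %6.1f mm (step-1 bifurcation at %.2f mm)\n",
              x$contact_window, bifurcation_diameter(x)))
  cat(sprintf("  max_time             %6.1f min, dt %.2f min, ds %.2f mm\n",
              x$max_time, x$dt, x$ds))
  cat(sprintf("  jitter_sd            %6.1f mm, seed %d\n", x$jitter_sd, x$seed))
  invisible(x)
}

#' Step-1 bifurcation diameter implied by the model parameters
#'
#' Contact is maintained through the minimum-angle curl exactly when the
#' support curvature `2 / diameter` is at least `theta_min` (in radians)
#' divided by the contact window, so the predicted boundary between
#' continuous coiling and a moving contact point is
#' `2 * contact_window / theta_min_rad`.
#'
#' @param params A `model_params` object.
#' @return Diameter in mm.
#' @export
bifurcation_diameter <- function(params) {
  2 * params$contact_window / (params$theta_min * pi / 180)
}

# maximum intrinsic bend per joint (degrees) outside an active contact window
free_cap_deg <- function(params) {
  params$ds * (2 / params$free_coil_diameter) * 180 / pi
}
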