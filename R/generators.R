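#' Seeded generators for synthetic marker tracks and coiling-success tables
#'
#' No raw marker coordinates or trial tables are deposited with the
#' experiments this package models, so every fixture the measurement pipeline
#' and the GLM need is generated here with stated kinematics, noise and
#' seeds: free-coil tracks emulating the 12-frame time-lapse protocol (one
#' picture every 60 s after a 60 s contact stimulus), wrap tracks emulating
#' the rapid-coiling-then-stop 3D tracking runs on thin and thick rods, and
#' Bernoulli coiling-success tables over the experimental support-diameter
#' grid.
#'
#' @name synthetic_data
#' @keywords internal
NULL

#' Track generator preset
#'
#' @param name Preset name.
#' @param tendril_length Tendril length in mm.
#' @param support_diameter Support (rod) diameter in mm (provenance only; the
#'   generated kinematics are parameterized by `stop_diameter`).
#' @param stop_diameter Coil diameter (mm) the track settles into during the
#'   stop stage.
#' @param theta_min Plateau coiling angle (degrees) for free-coil tracks.
#' @param n_frames Number of frames.
#' @param frame_interval Frame spacing in minutes.
#' @param marker_spacing Marker arc-length spacing in mm.
#' @param noise_sd Isotropic Gaussian marker noise, mm (0 = noiseless).
#' @param seed Integer seed.
#' @return A validated `track_preset` object.
#' @export
track_preset <- function(name, tendril_length, support_diameter = NA,
                         stop_diameter = NA, theta_min = 25, n_frames = 12L,
                         frame_interval = 1, marker_spacing = 5,
                         noise_sd = 0, seed = 1L) {
  chk <- function(cond, field) {
    if (!isTRUE(cond)) stop(sprintf("invalid preset field: %s", field),
                            call. = FALSE)
  }
  chk(is.character(name) && length(name) == 1L, "name")
  chk(is.finite(tendril_length) && tendril_length > 0, "tendril_length")
  chk(is.na(support_diameter) ||
        (is.finite(support_diameter) && support_diameter > 0),
      "support_diameter")
  chk(is.na(stop_diameter) || (is.finite(stop_diameter) && stop_diameter > 0),
      "stop_diameter")
  chk(is.finite(theta_min) && theta_min > 0 && theta_min <= 180, "theta_min")
  chk(is.numeric(n_frames) && n_frames >= 2, "n_frames")
  chk(is.finite(frame_interval) && frame_interval > 0, "frame_interval")
  chk(is.finite(marker_spacing) && marker_spacing > 0, "marker_spacing")
  chk(is.finite(noise_sd) && noise_sd >= 0, "noise_sd")
  structure(list(name = name, tendril_length = tendril_length,
                 support_diameter = support_diameter,
                 stop_diameter = stop_diameter, theta_min = theta_min,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 marker_spacing = marker_spacing, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "track_preset")
}

#' Named wrap-track presets
#'
#' `fig5_thin`: an 89 mm tendril coiling on a 1 mm rod, settling into a
#' 20.4 mm coil. `fig6_thick`: a 69 mm tendril on a 40 mm rod, settling into
#' a 16.1 mm coil.
#'
#' @param name Preset name; with no argument, the list of all presets.
#' @return A `track_preset`, or a named list of presets.
#' @export
wrap_preset <- function(name = NULL) {
  presets <- list(
    fig5_thin = track_preset("fig5_thin", tendril_length = 89,
                             support_diameter = 1, stop_diameter = 20.4,
                             n_frames = 21L),
    fig6_thick = track_preset("fig6_thick", tendril_length = 69,
                              support_diameter = 40, stop_diameter = 16.1,
                              n_frames = 21L)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop(sprintf("unknown preset '%s' (available: %s)", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  presets[[name]]
}

with_seed <- function(seed, expr) {
  has_rng <- exists(".Random.seed", envir = globalenv())
  if (has_rng) old_seed <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_rng) assign(".Random.seed", old_seed, envir = globalenv())
  })
  expr
}

add_marker_noise <- function(frames, sd) {
  if (sd <= 0) return(frames)
  lapply(frames, function(f) f + matrix(stats::rnorm(length(f), 0, sd),
                                        nrow(f), ncol(f)))
}

#' Generate a free-coil marker track
#'
#' Emulates the time-lapse protocol in which a tendril is stimulated by a
#' brief contact, the support removed, and the coiling angle photographed at
#' fixed intervals: a straight tendril accrues bend at the contact marker
#' along a saturating ramp that reaches the plateau `theta_min` after
#' one-third of the frames and holds it. Defaults: 12 frames at 1-minute
#' spacing, markers every 5 mm, noiseless.
#'
#' @param preset A `track_preset`; `stop_diameter` is ignored.
#' @return A `marker_track` whose coiling-angle series at the contact marker
#'   ramps from 0 to exactly `theta_min`.
#' @export
gen_free_coil_track <- function(preset = track_preset("free_coil",
                                                      tendril_length = 60)) {
  stopifnot(inherits(preset, "track_preset"))
  s <- preset$marker_spacing
  m <- as.integer(floor(preset$tendril_length / s)) + 1L
  if (m < 3L) stop("invalid preset field: tendril_length (needs >= 3 markers)",
                   call. = FALSE)
  cidx <- as.integer(ceiling(m / 2))
  ramp <- max(1L, as.integer(ceiling(preset$n_frames / 3)))
  frames <- lapply(seq_len(preset$n_frames), function(k) {
    theta <- preset$theta_min * min(1, (k - 1L) / ramp)
    th <- theta * pi / 180
    pos <- matrix(0, m, 3)
    pos[seq_len(cidx), 1] <- (seq_len(cidx) - 1L) * s
    if (cidx < m) {
      j <- seq.int(cidx + 1L, m)
      pos[j, 1] <- pos[cidx, 1] + (j - cidx) * s * cos(th)
      pos[j, 2] <- (j - cidx) * s * sin(th)
    }
    pos
  })
  frames <- with_seed(preset$seed, add_marker_noise(frames, preset$noise_sd))
  marker_track(frames, (seq_len(preset$n_frames) - 1L) * preset$frame_interval,
               marker_spacing = s,
               meta = sprintf("synthetic free-coil track '%s'", preset$name))
}

#' Generate a wrap marker track
#'
#' Emulates a 3D-tracked coiling run: the tendril region from the contact
#' marker to the tip winds onto a circle whose diameter shrinks from infinity
#' (straight) to `stop_diameter` following a saturating exponential ramp
#' (at least 80 percent of the final curvature is reached by one-third of the
#' frames, and the final curvature is held exactly from half of the frames
#' on), giving the rapid-coiling-then-stop shape. Markers sit at
#' exact arc-length multiples of `marker_spacing` on the current circle.
#'
#' @param preset A `track_preset` with `stop_diameter` set, or a preset name
#'   accepted by [wrap_preset()].
#' @return A `marker_track`.
#' @export
gen_wrap_track <- function(preset = "fig5_thin") {
  if (is.character(preset)) preset <- wrap_preset(preset)
  stopifnot(inherits(preset, "track_preset"))
  if (is.na(preset$stop_diameter)) {
    stop("invalid preset field: stop_diameter (required for wrap tracks)",
         call. = FALSE)
  }
  s <- preset$marker_spacing
  if (preset$stop_diameter < 2 * s / pi) {
    stop(sprintf(
      "invalid preset field: stop_diameter (%.3g mm is unresolvable by markers %g mm apart)",
      preset$stop_diameter, s), call. = FALSE)
  }
  m <- as.integer(floor(preset$tendril_length / s)) + 1L
  if (m < 5L) stop("invalid preset field: tendril_length (needs >= 5 markers)",
                   call. = FALSE)
  cidx <- as.integer(ceiling(m / 2))
  Tn <- preset$n_frames
  k_ramp <- as.integer(ceiling(Tn / 2))
  k_third <- as.integer(ceiling(Tn / 3))
  # exponential-approach rate chosen so at least 80 percent of the final
  # curvature is reached by one third of the frames (and held exactly from
  # k_ramp on)
  frac_at <- function(r, k) {
    if (k >= k_ramp) return(1)
    (1 - exp(-r * (k - 1L))) / (1 - exp(-r * (k_ramp - 1L)))
  }
  r <- if (k_third >= k_ramp) 1 else {
    stats::uniroot(function(r) frac_at(r, k_third) - 0.82,
                   c(1e-3, 20), tol = 1e-10)$root
  }
  frac <- function(k) frac_at(r, k)
  kappa_final <- 2 / preset$stop_diameter
  frames <- lapply(seq_len(Tn), function(k) {
    f <- frac(k)
    pos <- matrix(0, m, 3)
    pos[seq_len(cidx), 1] <- (seq_len(cidx) - 1L) * s
    if (cidx < m) {
      j <- seq.int(cidx + 1L, m)
      if (f <= 0) {
        pos[j, 1] <- pos[cidx, 1] + (j - cidx) * s
      } else {
        rho <- 1 / (f * kappa_final)
        ctr <- c(pos[cidx, 1], rho)
        ang <- -pi / 2 + (j - cidx) * s / rho
        pos[j, 1] <- ctr[1] + rho * cos(ang)
        pos[j, 2] <- ctr[2] + rho * sin(ang)
      }
    }
    pos
  })
  frames <- with_seed(preset$seed, add_marker_noise(frames, preset$noise_sd))
  marker_track(frames, (seq_len(Tn) - 1L) * preset$frame_interval,
               marker_spacing = s,
               meta = sprintf("synthetic wrap track '%s'", preset$name))
}

#' Configuration for the coiling-success generator
#'
#' Defaults emulate the coiling experiment: 87 trials over the nine-value
#' support-diameter grid (10-35 mm), tendril lengths uniform over 60-160 mm,
#' and logistic coefficients chosen so success is less likely on thick
#' supports and more likely for long tendrils, with failures concentrated at
#' the large-diameter, short-length corner.
#'
#' @param n_trials Number of trials. Default 87.
#' @param diameter_grid Support diameters (mm) sampled uniformly.
#' @param length_range Tendril length range (mm), sampled uniformly.
#' @param beta0 Intercept on the logit scale.
#' @param beta_diameter Diameter coefficient, logit per mm (negative).
#' @param beta_length Length coefficient, logit per mm (positive).
#' @param seed Integer seed.
#' @return A validated `success_gen_config` object.
#' @export
success_gen_config <- function(n_trials = 87L,
                               diameter_grid = c(10, 12, 15, 18, 20, 24, 30,
                                                 32, 35),
                               length_range = c(60, 160),
                               beta0 = 0, beta_diameter = -0.25,
                               beta_length = 0.05, seed = 1L) {
  chk <- function(cond, field) {
    if (!isTRUE(cond)) stop(sprintf("invalid config field: %s", field),
                            call. = FALSE)
  }
  chk(is.numeric(n_trials) && n_trials >= 1, "n_trials")
  chk(length(diameter_grid) >= 1L && all(diameter_grid > 0), "diameter_grid")
  chk(length(length_range) == 2L && all(length_range > 0) &&
        length_range[1] <= length_range[2], "length_range")
  chk(is.finite(beta0), "beta0")
  chk(is.finite(beta_diameter), "beta_diameter")
  chk(is.finite(beta_length), "beta_length")
  structure(list(n_trials = as.integer(n_trials),
                 diameter_grid = diameter_grid, length_range = length_range,
                 beta0 = beta0, beta_diameter = beta_diameter,
                 beta_length = beta_length, seed = as.integer(seed)),
            class = "success_gen_config")
}

#' Generate a coiling-success dataset
#'
#' Draws the support diameter uniformly from the grid and the tendril length
#' uniformly from its range, then draws success from a Bernoulli with
#' probability `plogis(beta0 + beta_diameter * D + beta_length * L)`.
#'
#' @param cfg A `success_gen_config`.
#' @return A data.frame of class `success_dataset` with columns
#'   `diameter_mm`, `length_mm`, `success` (0/1).
#' @export
gen_success_dataset <- function(cfg = success_gen_config()) {
  stopifnot(inherits(cfg, "success_gen_config"))
  with_seed(cfg$seed, {
    d <- sample(cfg$diameter_grid, cfg$n_trials, replace = TRUE)
    l <- stats::runif(cfg$n_trials, cfg$length_range[1], cfg$length_range[2])
    p <- stats::plogis(cfg$beta0 + cfg$beta_diameter * d + cfg$beta_length * l)
    y <- stats::rbinom(cfg$n_trials, 1L, p)
    out <- data.frame(diameter_mm = d, length_mm = l, success = y)
    class(out) <- c("success_dataset", "data.frame")
    out
  })
}

#' Read or write a coiling-success dataset CSV
#'
#' Columns `diameter_mm`, `length_mm`, `success`.
#'
#' @param path CSV path.
#' @return For the reader, a `success_dataset` data.frame.
#' @export
read_success_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("diameter_mm", "length_mm", "success")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  validate_success_dataset(df)
  class(df) <- c("success_dataset", "data.frame")
  df
}

#' @rdname read_success_csv
#' @param data A `success_dataset` data.frame.
#' @export
write_success_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

validate_success_dataset <- function(data) {
  if (nrow(data) < 1L) stop("empty success dataset", call. = FALSE)
  if (any(!is.finite(data$diameter_mm)) || any(data$diameter_mm <= 0)) {
    stop("diameter_mm must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(data$length_mm)) || any(data$length_mm <= 0)) {
    stop("length_mm must be positive and finite", call. = FALSE)
  }
  if (!all(data$success %in% c(0L, 1L))) {
    stop("success must be 0 or 1", call. = FALSE)
  }
  invisible(data)
}
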