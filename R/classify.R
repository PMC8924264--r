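#' Classify a simulated trial into the three-step phase decision tree
#'
#' Step 1 (initial response, scored within the first 5 minutes of coiling):
#' `continuous_coiling` if the contact node never moves more than one node
#' from the initial contact, else `moving_contact_point`. Step 2 (only for
#' moving trials): `clip_shape_coiling` if a secondary contact at the root
#' occurred, otherwise `tip_contact`. Step 3: `success` if the wrap closed
#' (total intrinsic wrap reached the threshold while attached), otherwise
#' `detach` with the detachment time.
#'
#' @param traj A `tendril_trajectory` from [simulate_coiling()].
#' @param params A `model_params` object (defaults to the trajectory's own).
#' @return An object of class `phase_record`: a list with `step1`, `step2`,
#'   `step3`, `time_to_detach` (minutes or NA), and `total_wrap` (degrees).
#' @export
classify_phases <- function(traj, params = traj$params) {
  if (!inherits(traj, "tendril_trajectory")) {
    stop("traj must be a tendril_trajectory", call. = FALSE)
  }
  if (!any(traj$events$event == "initial_contact")) {
    stop("no coiling started: trajectory has no initial_contact event",
         call. = FALSE)
  }
  t0 <- traj$events$time[traj$events$event == "initial_contact"][1]
  early <- which(traj$times - t0 < 5 & !is.na(traj$contact))
  c0 <- traj$contact[early[1]]
  moved <- any(abs(traj$contact[early] - c0) > 1L)
  step1 <- if (moved) "moving_contact_point" else "continuous_coiling"

  step2 <- if (step1 == "continuous_coiling") {
    "not_applicable"
  } else if (any(traj$events$event == "secondary_contact_root")) {
    "clip_shape_coiling"
  } else {
    "tip_contact"
  }

  step3 <- if (traj$wrap_closed) "success" else "detach"
  ttd <- if (step3 == "detach") {
    if (is.na(traj$detach_time)) max(traj$times) else traj$detach_time
  } else {
    NA_real_
  }

  structure(list(step1 = step1, step2 = step2, step3 = step3,
                 time_to_detach = ttd, total_wrap = traj$total_wrap),
            class = "phase_record")
}

#' @export
print.phase_record <- function(x, ...) {
  cat(sprintf("Phase record: %s -> %s -> %s\n", x$step1, x$step2, x$step3))
  if (!is.na(x$time_to_detach)) {
    cat(sprintf("  detached at %.1f min\n", x$time_to_detach))
  }
  cat(sprintf("  total wrap %.1f deg\n", x$total_wrap))
  invisible(x)
}

#' @export
as.data.frame.phase_record <- function(x, ...) {
  data.frame(step1 = x$step1, step2 = x$step2, step3 = x$step3,
             time_to_detach = x$time_to_detach, total_wrap = x$total_wrap,
             stringsAsFactors = FALSE)
}

#' Sweep tendril length and support diameter
#'
#' Runs one trial per (length, diameter, seed) cell of the full-factorial
#' grid and classifies each into the three-step phase tree. Errors in a cell
#' are recorded in the `error` column rather than aborting the sweep.
#'
#' @param lengths Tendril lengths in mm.
#' @param diameters Support diameters in mm.
#' @param params A `model_params` object (its `seed` is replaced per cell).
#' @param seeds Integer seeds; one trial is run per seed per cell.
#' @return A tidy data.frame with one row per trial: `length_mm`,
#'   `diameter_mm`, `seed`, the three phase steps, `time_to_detach`,
#'   `total_wrap`, and `error`.
#' @export
phase_diagram <- function(lengths, diameters, params = model_params(),
                          seeds = 1L) {
  if (length(lengths) == 0L || length(diameters) == 0L) {
    stop("lengths and diameters must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(length_mm = lengths, diameter_mm = diameters,
                      seed = as.integer(seeds), KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    p <- params
    p$seed <- g$seed
    rec <- tryCatch({
      traj <- simulate_coiling(g$length_mm, g$diameter_mm, p)
      pr <- classify_phases(traj, p)
      cbind(g, as.data.frame(pr), error = NA_character_)
    }, error = function(e) {
      cbind(g, data.frame(step1 = NA_character_, step2 = NA_character_,
                          step3 = NA_character_, time_to_detach = NA_real_,
                          total_wrap = NA_real_,
                          error = conditionMessage(e)))
    })
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a trajectory as tidy CSV files
#'
#' Writes the node positions (`time_min`, `node_id`, `x_mm`, `y_mm`, `z_mm`,
#' `contact_flag`) and, optionally, the event log (`time_min`, `event`,
#' `node`).
#'
#' @param traj A `tendril_trajectory`.
#' @param path Output CSV path for the node table.
#' @param events_path Optional output CSV path for the event log.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, events_path = NULL) {
  tabs <- lapply(seq_along(traj$times), function(k) {
    pos <- traj$frames[[k]]
    data.frame(time_min = traj$times[k], node_id = seq_len(nrow(pos)) - 1L,
               x_mm = pos[, 1], y_mm = pos[, 2], z_mm = 0,
               contact_flag = as.integer(seq_len(nrow(pos)) ==
                                           traj$contact[k] &
                                           !is.na(traj$contact[k])))
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  if (!is.null(events_path)) {
    ev <- traj$events
    names(ev) <- c("time_min", "event", "node")
    utils::write.csv(ev, events_path, row.names = FALSE)
  }
  invisible(path)
}

#' Export a trajectory as a marker track
#'
#' Resamples every stored frame at `marker_spacing` arc-length intervals so
#' the simulator output can be fed through the same measurement pipeline as
#' tracked experimental markers. The planar simulation is embedded in 3D with
#' an optional out-of-plane pitch per marker so that multi-wrap coils do not
#' self-intersect.
#'
#' @param traj A `tendril_trajectory`.
#' @param marker_spacing Arc-length spacing of virtual markers in mm.
#' @param pitch Out-of-plane rise (mm) per marker. Default 0.
#' @return A `marker_track` object.
#' @export
trajectory_to_track <- function(traj, marker_spacing = 5, pitch = 0) {
  frames <- lapply(traj$frames, function(pos) {
    m <- resample_polyline(cbind(pos, 0), marker_spacing)
    if (pitch != 0) m[, 3] <- m[, 3] + pitch * (seq_len(nrow(m)) - 1L)
    m
  })
  nm <- min(vapply(frames, nrow, integer(1)))
  frames <- lapply(frames, function(m) m[seq_len(nm), , drop = FALSE])
  marker_track(frames, traj$times, marker_spacing,
               meta = "resampled from simulated trajectory")
}
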