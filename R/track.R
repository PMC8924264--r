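#' Marker tracks and the measurement pipeline
#'
#' A `marker_track` holds time-indexed 3D coordinates of markers painted at
#' fixed arc-length intervals along a tendril, as produced by image-based 3D
#' motion tracking. The pipeline computes per-marker bending-angle series,
#' the coiling-angle time course at the contact marker, segments the rapid
#' coiling stage from the stop stage, and estimates the stop-stage coil
#' diameter by circle fitting.
#'
#' @name track_analysis
#' @keywords internal
NULL

#' Construct a marker track
#'
#' @param frames List of per-frame marker coordinate matrices (m x 3, root
#'   marker first); every frame must have the same marker count, m >= 3.
#' @param frame_times Strictly increasing frame times in minutes.
#' @param marker_spacing Nominal arc-length spacing of the markers in mm.
#' @param meta Free-text provenance.
#' @return An object of class `marker_track`.
#' @export
marker_track <- function(frames, frame_times, marker_spacing = 5, meta = "") {
  if (length(frames) != length(frame_times)) {
    stop("frames and frame_times must have the same length", call. = FALSE)
  }
  if (length(frames) < 1L) stop("need at least one frame", call. = FALSE)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) == 2L) f <- cbind(f, 0)
    if (!all(is.finite(f))) stop("non-finite marker coordinates", call. = FALSE)
    f
  })
  m <- nrow(frames[[1]])
  if (m < 3L) stop("need at least 3 markers", call. = FALSE)
  if (!all(vapply(frames, nrow, integer(1)) == m)) {
    stop("every frame must have the same marker count", call. = FALSE)
  }
  if (any(diff(frame_times) <= 0)) {
    stop("frame_times must be strictly increasing", call. = FALSE)
  }
  structure(list(frames = frames, frame_times = as.numeric(frame_times),
                 marker_spacing = marker_spacing, meta = meta),
            class = "marker_track")
}

#' @export
print.marker_track <- function(x, ...) {
  cat(sprintf("Marker track: %d markers x %d frames (%.1f-%.1f min), %g mm spacing\n",
              nrow(x$frames[[1]]), length(x$frames), min(x$frame_times),
              max(x$frame_times), x$marker_spacing))
  if (nzchar(x$meta)) cat(" ", x$meta, "\n")
  invisible(x)
}

n_markers <- function(track) nrow(track$frames[[1]])

#' Bending-angle series of a marker track
#'
#' For every frame and every interior marker i, the interior angle at marker
#' i between its two neighbours, in degrees (180 = locally straight). The two
#' end markers have no bending angle. Degenerate marker triples (coincident
#' neighbours) give NA for that cell with a warning rather than an abort.
#'
#' @param track A `marker_track`.
#' @return A frames x (markers - 2) matrix of class `bending_series`;
#'   column j corresponds to marker j + 1.
#' @export
bending_series <- function(track) {
  m <- n_markers(track)
  nt <- length(track$frames)
  out <- matrix(NA_real_, nt, m - 2L)
  n_bad <- 0L
  for (t in seq_len(nt)) {
    f <- track$frames[[t]]
    for (i in 2:(m - 1L)) {
      v <- tryCatch(bending_angle(f[i - 1L, ], f[i, ], f[i + 1L, ]),
                    error = function(e) NA_real_)
      if (is.na(v)) n_bad <- n_bad + 1L
      out[t, i - 1L] <- v
    }
  }
  if (n_bad > 0L) {
    warning(sprintf("%d degenerate marker triple(s) set to NA", n_bad),
            call. = FALSE)
  }
  colnames(out) <- paste0("marker_", 2:(m - 1L))
  class(out) <- c("bending_series", class(out))
  out
}

#' Coiling-angle time course at the contact marker
#'
#' Per-frame coiling angle (180 minus the bending angle) at the contact
#' marker, plus the plateau value: the mean over the detected stop stage.
#'
#' @param track A `marker_track`.
#' @param contact_index Interior marker index (1-based) of the contact point.
#' @param stop_eps,persistence Stage-segmentation settings, see
#'   [segment_stages()].
#' @return A list with `series` (degrees per frame), `plateau` (mean over
#'   the stop window, or NA when no stop stage was found), and `segmentation`.
#' @export
coiling_angle_series <- function(track, contact_index, stop_eps = 1,
                                 persistence = 3) {
  m <- n_markers(track)
  if (contact_index <= 1L || contact_index >= m) {
    stop("contact_index must be an interior marker", call. = FALSE)
  }
  series <- vapply(track$frames,
                   function(f) coiling_angle_at(f, contact_index),
                   numeric(1))
  seg <- segment_stages(series, stop_eps = stop_eps, persistence = persistence)
  plateau <- if (is.null(seg$stop_window)) NA_real_ else {
    mean(series[seg$stop_window[1]:seg$stop_window[2]])
  }
  list(series = series, plateau = plateau, segmentation = seg)
}

#' Segment a coiling series into the rapid stage and the stop stage
#'
#' The stop stage starts at the first frame from which the absolute
#' frame-to-frame change stays below `stop_eps` for at least `persistence`
#' consecutive frame transitions; the transform (rapid coiling) window spans
#' from the first motion to the frame before the stop starts.
#'
#' @param series Numeric per-frame series in degrees (e.g. a coiling-angle
#'   series or one marker's bending-angle column).
#' @param stop_eps Per-frame angle change (degrees) below which the tendril
#'   counts as stopped. Default 1.
#' @param persistence Minimum number of consecutive quiet transitions.
#'   Default 3.
#' @return An object of class `stage_segmentation`: `transform_window` and
#'   `stop_window`, each a (start, end) frame pair; `stop_window` is NULL
#'   when no quiet run exists, `transform_window` is NULL when the series
#'   never moves.
#' @export
segment_stages <- function(series, stop_eps = 1, persistence = 3) {
  series <- as.numeric(series)
  nt <- length(series)
  if (nt < persistence + 2L) {
    stop(sprintf("need at least %d frames to segment stages", persistence + 2L),
         call. = FALSE)
  }
  quiet <- abs(diff(series)) < stop_eps # length nt - 1
  stop_start <- NA_integer_
  run <- 0L
  for (k in seq_along(quiet)) {
    run <- if (quiet[k]) run + 1L else 0L
    if (run == persistence) {
      s <- k - persistence + 1L
      # extend back: the stop starts at the first frame of this quiet run
      stop_start <- s
      break
    }
  }
  if (!is.na(stop_start)) {
    # the run must continue to the end to count as the terminal stop stage;
    # otherwise keep scanning from the interruption
    k <- stop_start
    repeat {
      while (k <= nt - 1L && quiet[k]) k <- k + 1L
      if (k > nt - 1L) break
      # interrupted: find the next run of `persistence` quiet transitions
      run <- 0L
      found <- NA_integer_
      for (j in seq.int(k + 1L, nt - 1L)) {
        run <- if (quiet[j]) run + 1L else 0L
        if (run == persistence) {
          found <- j - persistence + 1L
          break
        }
      }
      if (is.na(found)) {
        stop_start <- NA_integer_
        break
      }
      stop_start <- found
      k <- found
    }
  }
  first_move <- which(abs(diff(series)) >= stop_eps)
  transform <- if (length(first_move) == 0L) NULL else {
    tr_end <- if (is.na(stop_start)) nt else stop_start
    as.integer(c(first_move[1], tr_end))
  }
  stopw <- if (is.na(stop_start)) NULL else as.integer(c(stop_start, nt))
  structure(list(transform_window = transform, stop_window = stopw),
            class = "stage_segmentation")
}

#' @export
print.stage_segmentation <- function(x, ...) {
  fmt <- function(w) if (is.null(w)) "none" else sprintf("frames %d-%d", w[1], w[2])
  cat("Stage segmentation:\n")
  cat("  rapid coiling:", fmt(x$transform_window), "\n")
  cat("  stop stage:   ", fmt(x$stop_window), "\n")
  invisible(x)
}

#' Coil diameter in the stop stage
#'
#' Fits a circle (plane projection + Pratt fit + geometric refinement) to the
#' coiled markers at the midpoint frame of the stop window and returns the
#' fitted diameter. Which markers form the coil is not always known a priori,
#' so `marker_subset` is explicit; by default the coiled markers are
#' auto-detected as those whose bending angle at the midpoint frame deviates
#' from straight by more than `bend_tol` degrees, together with their
#' flanking markers.
#'
#' @param track A `marker_track`.
#' @param seg A `stage_segmentation` with a stop window (e.g. from
#'   [segment_stages()] on the track's aggregate bending series).
#' @param marker_subset Integer marker indices to fit, or NULL to
#'   auto-detect the coiled region.
#' @param bend_tol Deviation from 180 degrees (default 5) above which a
#'   marker counts as coiled when auto-detecting.
#' @param average_frames If TRUE, average the fitted diameter over every
#'   stop-window frame instead of using the single midpoint frame.
#' @return The fitted `circle_fit` object; its `diameter` is the stop-stage
#'   coil diameter in mm.
#' @export
stop_stage_diameter <- function(track, seg, marker_subset = NULL,
                                bend_tol = 5, average_frames = FALSE) {
  if (is.null(seg$stop_window)) {
    stop("no stop stage detected: cannot measure a stop-stage diameter",
         call. = FALSE)
  }
  mid <- floor(mean(seg$stop_window))
  if (is.null(marker_subset)) {
    f <- track$frames[[mid]]
    m <- nrow(f)
    bend <- vapply(2:(m - 1L), function(i) {
      tryCatch(bending_angle(f[i - 1L, ], f[i, ], f[i + 1L, ]),
               error = function(e) NA_real_)
    }, numeric(1))
    dev <- 180 - bend
    if (all(is.na(dev)) || max(dev, na.rm = TRUE) <= bend_tol) {
      stop("no coiled markers found; supply marker_subset explicitly",
           call. = FALSE)
    }
    # adaptive threshold: marker noise can push straight markers past a
    # small fixed tolerance, so require at least half the strongest bend,
    # and keep only the contiguous run around it
    thr <- max(bend_tol, max(dev, na.rm = TRUE) / 2)
    hot <- !is.na(dev) & dev > thr
    k <- which.max(dev)
    lo <- k
    while (lo > 1L && hot[lo - 1L]) lo <- lo - 1L
    hi <- k
    while (hi < length(hot) && hot[hi + 1L]) hi <- hi + 1L
    # interior marker i sits at bend column i - 1; the tip-ward end marker
    # rides on the coil, while the marker root-ward of the first bent one
    # still lies on the straight part and would bias the fit
    marker_subset <- seq.int(lo + 1L, min(hi + 2L, m))
  }
  fit_one <- function(k) fit_circle_3d(track$frames[[k]][marker_subset, ,
                                                         drop = FALSE])
  if (!average_frames) return(fit_one(mid))
  fits <- lapply(seg$stop_window[1]:seg$stop_window[2], fit_one)
  fit <- fit_one(mid)
  fit$diameter <- mean(vapply(fits, `[[`, numeric(1), "diameter"))
  fit
}

#' Full analysis report for a marker track
#'
#' Runs the whole measurement pipeline: bending-angle series, stage
#' segmentation on the mean interior bending angle, coiling-angle time
#' course at the contact marker, and the stop-stage coil diameter.
#'
#' @param track A `marker_track`.
#' @param contact_index Interior contact marker; defaults to the middle
#'   marker.
#' @param stop_eps,persistence Stage-segmentation settings.
#' @param marker_subset Markers for the circle fit (NULL = auto-detect).
#' @return A list of class `track_report` with the plateau coiling angle,
#'   stage windows, stop-stage diameter and circle fit, and the series.
#' @export
analyze_track <- function(track, contact_index = NULL, stop_eps = 1,
                          persistence = 3, marker_subset = NULL) {
  m <- n_markers(track)
  if (is.null(contact_index)) contact_index <- as.integer(ceiling(m / 2))
  bs <- bending_series(track)
  agg <- rowMeans(bs, na.rm = TRUE)
  seg <- segment_stages(agg, stop_eps = stop_eps, persistence = persistence)
  ca <- coiling_angle_series(track, contact_index, stop_eps = stop_eps,
                             persistence = persistence)
  fit <- if (is.null(seg$stop_window)) NULL else {
    tryCatch(stop_stage_diameter(track, seg, marker_subset = marker_subset),
             error = function(e) NULL)
  }
  structure(
    list(contact_index = contact_index,
         plateau_angle = ca$plateau,
         segmentation = seg,
         stop_stage_diameter = if (is.null(fit)) NA_real_ else fit$diameter,
         circle_fit = fit,
         coiling_series = ca$series,
         bending = bs),
    class = "track_report"
  )
}

#' @export
print.track_report <- function(x, ...) {
  cat("Track analysis report\n")
  cat(sprintf("  contact marker        %d\n", x$contact_index))
  cat(sprintf("  plateau coiling angle %.2f deg\n", x$plateau_angle))
  print(x$segmentation)
  cat(sprintf("  stop-stage diameter   %.2f mm\n", x$stop_stage_diameter))
  invisible(x)
}

#' Write a track analysis report as JSON
#'
#' @param report A `track_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_track_report <- function(report, path) {
  out <- list(
    contact_index = report$contact_index,
    plateau_angle_deg = report$plateau_angle,
    transform_window = report$segmentation$transform_window,
    stop_window = report$segmentation$stop_window,
    stop_stage_diameter_mm = report$stop_stage_diameter,
    coiling_series_deg = report$coiling_series
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# ---- CSV dialect ------------------------------------------------------------

#' Read a marker track from CSV
#'
#' Expects the columns `frame`, `time_min`, `marker_id`, `x_mm`, `y_mm`,
#' `z_mm` (header required, `marker_id` 0-based from the root). Invariants
#' (equal marker counts per frame, strictly increasing times) are validated
#' and violations reported with the offending row.
#'
#' @param path CSV path.
#' @param marker_spacing Nominal marker spacing in mm (default 5).
#' @return A `marker_track`.
#' @export
read_track_csv <- function(path, marker_spacing = 5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_min", "marker_id", "x_mm", "y_mm", "z_mm")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric or missing value at data row %d of %s", bad[1],
                 path), call. = FALSE)
  }
  frames_id <- sort(unique(df$frame))
  frames <- lapply(frames_id, function(fr) {
    sub <- df[df$frame == fr, ]
    sub <- sub[order(sub$marker_id), ]
    m <- as.matrix(sub[, c("x_mm", "y_mm", "z_mm")])
    dimnames(m) <- NULL
    m
  })
  times <- vapply(frames_id, function(fr) df$time_min[df$frame == fr][1],
                  numeric(1))
  marker_track(frames, times, marker_spacing = marker_spacing,
               meta = paste("read from", path))
}

#' Write a marker track to CSV
#'
#' Writes the dialect read by [read_track_csv()]: columns `frame`,
#' `time_min`, `marker_id` (0-based from the root), `x_mm`, `y_mm`, `z_mm`.
#'
#' @param track A `marker_track`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  m <- n_markers(track)
  tabs <- lapply(seq_along(track$frames), function(k) {
    f <- track$frames[[k]]
    data.frame(frame = k - 1L, time_min = track$frame_times[k],
               marker_id = seq_len(m) - 1L,
               x_mm = f[, 1], y_mm = f[, 2], z_mm = f[, 3])
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}
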