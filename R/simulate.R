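#' Quasi-static planar simulator of the two-rule coiling model
#'
#' The tendril is an inextensible chain of nodes spaced `ds` apart with an
#' intrinsic bend (degrees, toward the contacted side) at every interior
#' joint; the support is a circle (the cross-section of the rod). Coiling is
#' driven by the two behavioural rules. Rule 1: bend is laid down around the
#' active contact point at `coiling_rate`. Rule 2: once coiling has started,
#' a minimum coiling angle `theta_min` is always expressed over the contact
#' window. When the support surface is curved at least as sharply as that
#' curl demands (`2/diameter >= theta_min_rad/contact_window`) the contact
#' holds and the tendril coils in place at its free-coil curvature around the
#' support (continuous coiling). Otherwise bend that would penetrate the
#' support is truncated at surface tangency, so the tendril conforms to the
#' surface and the contact point migrates toward the tip, with a liftoff and
#' re-contact event each time `theta_min` of new bend accumulates (moving
#' contact point). Once the moving phase begins, coiling also propagates
#' toward the root at the free-coil curvature, bringing the root-side
#' segment toward the support; circumnutation (a seeded Gaussian sway of
#' amplitude `jitter_sd`) can then press the root quarter of the tendril
#' onto the support, and a sway exceeding the current root-quarter clearance
#' for `secondary_persistence` consecutive steps is a secondary contact at
#' the root, producing clip-shape coiling. Coiling succeeds when the wrap
#' closes around the support: in continuous coiling and clip-shape trials
#' when the total intrinsic wrap reaches `detach_wrap_threshold`, in
#' moving-contact trials when the conformed wrap arc itself covers that
#' angle; a moving contact that runs off the tip without a secondary contact
#' detaches.
#'
#' @name coil_model
#' @keywords internal
NULL

#' Create a straight tendril state
#'
#' @param length Tendril length in mm (> 2 * ds). Rounded to a whole number
#'   of segments.
#' @param ds Node spacing in mm.
#' @return An object of class `tendril_state`: nodes (n x 3 matrix, root
#'   first), `ds`, `joint_bend` (degrees per node, zero at the two ends),
#'   `length`, and `active_contact` (node index or NA).
#' @export
tendril_state <- function(length, ds = 1) {
  if (!is.finite(length) || length <= 2 * ds) {
    stop("length must be > 2 * ds mm", call. = FALSE)
  }
  n <- as.integer(round(length / ds)) + 1L
  nodes <- cbind(seq(0, by = ds, length.out = n), 0, 0)
  structure(list(nodes = nodes, ds = ds, joint_bend = numeric(n),
                 length = (n - 1L) * ds, active_contact = NA_integer_),
            class = "tendril_state")
}

#' Create a circular support cross-section
#'
#' @param diameter Support diameter in mm (> 0).
#' @param center (x, y) or (x, y, z) position of the circle center in mm.
#' @return An object of class `coil_support`.
#' @export
coil_support <- function(diameter, center = c(0, 0, 0)) {
  if (!is.finite(diameter) || diameter <= 0) {
    stop("support diameter must be > 0 mm", call. = FALSE)
  }
  center <- as_point3(center, "support center")
  structure(list(center = center, diameter = diameter), class = "coil_support")
}

#' Find the tendril node in contact with the support
#'
#' Returns the smallest (root-most) node index whose distance to the support
#' surface is at most `contact_tol`; nodes penetrating the support are
#' projected to the surface before the test, so they always qualify.
#'
#' @param state A `tendril_state`.
#' @param support A `coil_support`.
#' @param contact_tol Contact distance threshold in mm.
#' @return Node index (1-based) or `NA_integer_` when no node touches.
#' @export
detect_contact <- function(state, support, contact_tol = 0.2) {
  d <- node_clearance(state$nodes[, 1:2, drop = FALSE], support)
  d <- pmax(d, 0) # penetrating nodes project to the surface
  idx <- which(d <= contact_tol)
  if (length(idx) == 0L) NA_integer_ else min(idx)
}

node_clearance <- function(pos, support) {
  sqrt((pos[, 1] - support$center[1])^2 + (pos[, 2] - support$center[2])^2) -
    support$diameter / 2
}

maintained_contact <- function(params, diameter) {
  (2 / diameter) >= (params$theta_min * pi / 180) / params$contact_window -
    1e-12
}

# clearance (mm, >= 0) between the root-quarter portion of the tendril and
# the support surface; the circumnutation sway must exceed this for a
# secondary root contact
root_quarter_clearance <- function(pos, sim) {
  p <- sim$params
  rootq <- which((seq_len(sim$n) - 1L) * sim$ds <=
                   p$root_contact_fraction * sim$L)
  cl <- node_clearance(pos[rootq, , drop = FALSE], sim$support)
  list(gap = max(0, min(cl)), node = rootq[which.min(cl)])
}

# ---- internal chain geometry -------------------------------------------------

# body-frame chain; turn_deg is a length-n vector of turning angles at each
# node (ends unused)
body_chain <- function(turn_deg, ds) {
  n <- length(turn_deg)
  tr <- turn_deg[2:(n - 1L)] * pi / 180
  dirs <- c(0, cumsum(tr)) # direction of each of the n-1 segments
  pos <- cbind(c(0, cumsum(ds * cos(dirs))), c(0, cumsum(ds * sin(dirs))))
  list(pos = pos, dirs = dirs)
}

rotate_about <- function(pos, pivot, gamma) {
  cg <- cos(gamma); sg <- sin(gamma)
  dx <- pos[, 1] - pivot[1]
  dy <- pos[, 2] - pivot[2]
  cbind(pivot[1] + cg * dx - sg * dy, pivot[2] + sg * dx + cg * dy)
}

# smallest root-side "reaction" rotation about the anchor node that keeps the
# root-side chain clear of the support; negative rotation (away from the
# coiling side) is preferred at equal magnitude. Deterministic.
solve_reaction <- function(pos, a, support, tol = 1e-9) {
  if (a <= 1L) return(list(pos = pos, reaction = 0, cleared = TRUE))
  root_idx <- seq_len(a - 1L)
  pivot <- pos[a, ]
  f <- function(g) {
    min(node_clearance(rotate_about(pos[root_idx, , drop = FALSE], pivot, g),
                       support))
  }
  if (f(0) >= -tol) return(list(pos = pos, reaction = 0, cleared = TRUE))
  step <- pi / 180
  for (g in seq_len(180L)) {
    for (sgn in c(-1, 1)) {
      hi <- sgn * g * step
      if (f(hi) >= 0) {
        lo <- sgn * (g - 1L) * step
        for (i in seq_len(60L)) {
          mid <- (lo + hi) / 2
          if (f(mid) >= 0) hi <- mid else lo <- mid
        }
        pos[root_idx, ] <- rotate_about(pos[root_idx, , drop = FALSE], pivot, hi)
        return(list(pos = pos, reaction = hi, cleared = TRUE))
      }
    }
  }
  # no rigid root-side rotation clears the support: the configuration is
  # jammed and the caller must truncate the bend that caused it
  gs <- seq(-pi, pi, by = step)
  best <- gs[which.max(vapply(gs, f, numeric(1)))]
  pos[root_idx, ] <- rotate_about(pos[root_idx, , drop = FALSE], pivot, best)
  list(pos = pos, reaction = best, cleared = FALSE)
}

# ---- internal simulation engine ---------------------------------------------

add_event <- function(sim, event, node = NA_integer_) {
  sim$events[[length(sim$events) + 1L]] <-
    list(time = sim$time, event = event, node = as.integer(node))
  sim
}

# sequentially fill joints outward from the stimulated region at the
# free-coil curvature cap; `budget` degrees per call and per side.
# `laid_root` reports how much bend the root side actually took up.
fill_spread <- function(sim, budget_root, budget_tip) {
  cap <- free_cap_deg(sim$params)
  b <- budget_root
  sim$laid_root <- 0
  while (b > 1e-12 && sim$spread$root_next >= 2L) {
    j <- sim$spread$root_next
    room <- cap - sim$bends[j]
    take <- min(room, b)
    if (take > 0) {
      sim$bends[j] <- sim$bends[j] + take
      sim$laid_root <- sim$laid_root + take
      b <- b - take
    }
    if (sim$bends[j] >= cap - 1e-9) sim$spread$root_next <- j - 1L else break
  }
  b <- budget_tip
  while (b > 1e-12 && sim$spread$tip_next <= sim$n - 1L) {
    j <- sim$spread$tip_next
    room <- cap - sim$bends[j]
    take <- min(room, b)
    if (take > 0) {
      sim$bends[j] <- sim$bends[j] + take
      b <- b - take
    }
    if (sim$bends[j] >= cap - 1e-9) sim$spread$tip_next <- j + 1L else break
  }
  sim
}

# conforming wrap: lay bend along the support surface tip-ward of the
# contact; per-joint bend equals the inscribed-chord turn of the support
# circle, so wrapped nodes sit exactly on the surface (the literal
# "truncated at surface tangency" limit). Returns the updated sim plus how
# much bend was actually laid (for the theta_min liftoff bookkeeping).
fill_advance <- function(sim, budget) {
  delta <- conform_deg(sim)
  laid <- 0
  while (budget > 1e-12 && sim$front <= sim$n - 1L) {
    j <- sim$front
    room <- delta - sim$bends[j]
    take <- min(room, budget)
    if (take > 0) {
      sim$bends[j] <- sim$bends[j] + take
      budget <- budget - take
      laid <- laid + take
    }
    if (sim$bends[j] >= delta - 1e-9) sim$front <- j + 1L else break
  }
  sim$laid <- laid
  sim
}

conform_deg <- function(sim) {
  R <- sim$support$diameter / 2
  2 * asin(min(1, sim$ds / (2 * R))) * 180 / pi
}

# root-ward coiling with contact truncation: if the bend laid this step
# leaves the root side jammed against the support (no rigid reaction
# rotation clears it), the increment is reverted -- the support blocks
# further root-ward curling
root_fill_guarded <- function(sim, budget) {
  saved <- list(bends = sim$bends, spread = sim$spread,
                secondary_wrap = sim$secondary_wrap)
  sim <- fill_spread(sim, budget, 0)
  if (sim$laid_root <= 0) return(sim)
  if (sim$clip || sim$mode == "hold") {
    sim$secondary_wrap <- sim$secondary_wrap + sim$laid_root
  }
  placed <- sim_positions(sim)
  if (!placed$cleared) {
    sim$bends <- saved$bends
    sim$spread <- saved$spread
    sim$secondary_wrap <- saved$secondary_wrap
    if (is.na(sim$jam_since)) sim$jam_since <- sim$time
  } else {
    sim$jam_since <- NA_real_
  }
  sim
}

init_sim <- function(length, support_diameter, params, contact_position) {
  n <- as.integer(round(length / params$ds)) + 1L
  if (n < 4L) stop("length must cover at least three segments", call. = FALSE)
  L <- (n - 1L) * params$ds
  c0 <- as.integer(round(contact_position * (n - 1L))) + 1L
  c0 <- min(max(c0, 2L), n - 1L)
  sim <- list(params = params, n = n, ds = params$ds, L = L,
              bends = numeric(n),
              time = 0, events = list(), clip = FALSE,
              sway_streak = 0L, done = FALSE,
              wrap_closed = FALSE, tip_reached = FALSE,
              detach_time = NA_real_, stim0 = c0, wrap_arc = 0,
              secondary_wrap = 0, laid_root = 0, jam_since = NA_real_,
              detached = FALSE,
              episode_acc = 0, prev_contact = c0, front = c0,
              spread = list(root_next = c0 - 1L, tip_next = c0 + 1L,
                            root_on = FALSE, tip_on = FALSE),
              times = numeric(0), frames = list(), contact_hist = integer(0))
  if (is.null(support_diameter)) {
    sim$support <- NULL
    sim$mode <- "free"
    sim$anchor <- NA_integer_
    sim$spread$tip_next <- c0 # the stimulated joint itself coils too
    sim$spread$root_on <- sim$spread$tip_on <- TRUE
  } else {
    x0 <- (c0 - 1L) * params$ds
    sim$support <- coil_support(support_diameter,
                                c(x0, support_diameter / 2, 0))
    sim$anchor <- c0
    sim$mode <- if (maintained_contact(params, support_diameter)) "curl"
                else "advance"
    if (sim$mode == "curl") {
      k <- max(1L, ceiling(params$contact_window / params$ds))
      sim$window <- intersect(seq.int(c0, c0 + k - 1L), 2:(n - 1L))
      sim$window_cap <- params$theta_min / k
    }
    sim <- add_event(sim, "initial_contact", c0)
  }
  sim
}

sim_positions <- function(sim) {
  body <- body_chain(sim$bends, sim$ds)
  if (is.null(sim$support)) {
    return(list(pos = body$pos, reaction = 0))
  }
  a <- sim$anchor
  R <- sim$support$diameter / 2
  O <- sim$support$center[1:2]
  alpha <- -pi / 2
  # outgoing segment sits half the anchor-joint turn above the tangent, so
  # both adjacent chords straddle the tangency symmetrically
  target_out <- (alpha + pi / 2) + (sim$bends[a] / 2) * pi / 180
  rot <- target_out - body$dirs[min(a, sim$n - 1L)]
  anchor_lab <- O + R * c(cos(alpha), sin(alpha))
  cg <- cos(rot); sg <- sin(rot)
  dx <- body$pos[, 1] - body$pos[a, 1]
  dy <- body$pos[, 2] - body$pos[a, 2]
  pos <- cbind(anchor_lab[1] + cg * dx - sg * dy,
               anchor_lab[2] + sg * dx + cg * dy)
  solve_reaction(pos, a, sim$support)
}

record_frame <- function(sim, pos) {
  k <- length(sim$times) + 1L
  sim$times[k] <- sim$time
  sim$frames[[k]] <- pos
  sim$contact_hist[k] <- if (is.na(sim$anchor)) NA_integer_ else {
    if (sim$detached) NA_integer_
    else if (sim$mode %in% c("advance", "hold", "done") && sim$tip_reached)
      min(sim$front, sim$n)
    else if (sim$mode %in% c("advance", "hold")) min(sim$front, sim$n)
    else sim$anchor
  }
  sim
}

finish_detach <- function(sim) {
  sim <- add_event(sim, "detach")
  sim$detach_time <- sim$time
  sim$done <- TRUE
  sim$detached <- TRUE
  sim$mode <- "done"
  sim
}

sim_step <- function(sim, dt) {
  if (sim$done) return(sim)
  sim$time <- sim$time + dt
  p <- sim$params
  budget <- p$coiling_rate * dt

  # 1. coiling program: intrinsic bend uptake
  if (sim$mode == "curl") {
    w <- sim$window
    inc <- budget / length(w)
    sim$bends[w] <- pmin(sim$bends[w] + inc, sim$window_cap)
    if (sum(sim$bends[w]) >= min(p$theta_min,
                                 sim$window_cap * length(w)) - 1e-9) {
      # rule 2 satisfied in place: continuous coiling around the support
      sim$mode <- "wrap"
      sim$spread$root_on <- sim$spread$tip_on <- TRUE
      sim$spread$root_next <- min(w) - 1L
      sim$spread$tip_next <- max(w) + 1L
    }
  } else if (sim$mode == "advance") {
    sim <- fill_advance(sim, budget)
    sim$episode_acc <- sim$episode_acc + sim$laid
    sim$wrap_arc <- sim$wrap_arc + sim$laid
    if (sim$episode_acc >= p$theta_min - 1e-9) {
      # the curl cannot stay on this surface: liftoff, re-contact tip-ward
      sim <- add_event(sim, "liftoff", sim$prev_contact)
      sim <- add_event(sim, "new_contact", min(sim$front, sim$n))
      sim$prev_contact <- min(sim$front, sim$n)
      sim$episode_acc <- sim$episode_acc - p$theta_min
      sim$spread$root_on <- TRUE # coiling now propagates root-ward too
    }
    if (sim$spread$root_on) {
      sim <- root_fill_guarded(sim, budget)
    }
    if (sim$front > sim$n - 1L &&
        sim$bends[sim$n - 1L] >= conform_deg(sim) - 1e-9) {
      sim$tip_reached <- TRUE
      sim <- add_event(sim, "tip_reached", sim$n)
      if (sim$clip) sim$mode <- "hold" else sim <- finish_detach(sim)
    }
  } else if (sim$mode %in% c("wrap", "hold")) {
    if (sim$spread$tip_on) {
      sim <- fill_spread(sim, 0, budget)
    }
    if (sim$spread$root_on) {
      sim <- root_fill_guarded(sim, budget)
    }
  } else if (sim$mode == "free") {
    sim <- fill_spread(sim, budget, budget)
  }

  # 2. placement (anchored at the initial tangency; root-side reaction hinge
  # keeps the curling root segment off the support)
  placed <- sim_positions(sim)
  pos <- placed$pos

  if (!is.null(sim$support)) {
    # secondary contact at the root: the circumnutation sway (Gaussian,
    # sd = jitter_sd) must exceed the current clearance between the root
    # quarter and the support for `secondary_persistence` consecutive steps
    if (!sim$clip && sim$mode == "advance" && sim$spread$root_on &&
        p$jitter_sd > 0) {
      rq <- root_quarter_clearance(pos, sim)
      pressed <- abs(stats::rnorm(1, 0, p$jitter_sd)) >= rq$gap
      sim$sway_streak <- if (pressed) sim$sway_streak + 1L else 0L
      if (sim$sway_streak >= p$secondary_persistence) {
        sim$clip <- TRUE
        sim <- add_event(sim, "secondary_contact_root", rq$node)
      }
    }

    # wrap closure = coiling success: the wrap encloses the support. In
    # continuous coiling the free coil (always tighter than the support)
    # encircles it once the total intrinsic wrap comes full circle. In the
    # moving phase only the conformed arc on the surface counts (the free
    # tails enclose nothing); after a secondary root contact the root-side
    # coil adds to the enclosure, but only when the support fits inside the
    # free coil (a coil of free_coil_diameter cannot get around a thicker
    # rod).
    clip_credit <- if (sim$clip &&
                       sim$support$diameter <= p$free_coil_diameter) {
      sim$secondary_wrap
    } else 0
    wrap_measure <- if (sim$mode %in% c("advance", "hold")) {
      sim$wrap_arc + clip_credit
    } else {
      sum(sim$bends)
    }
    if (!sim$done && sim$mode %in% c("advance", "wrap", "hold") &&
        wrap_measure >= p$detach_wrap_threshold - 1e-9) {
      sim <- add_event(sim, "wrap_closed")
      sim$wrap_closed <- TRUE
      sim$done <- TRUE
      sim$mode <- "done"
    }

    # a clip whose coiling capacity is exhausted short of closure lets go:
    # either the root side is fully curled, or it has been jammed against
    # the support for longer than detach_persistence
    if (!sim$done && sim$mode == "hold" &&
        (sim$spread$root_next < 2L ||
           (!is.na(sim$jam_since) &&
              sim$time - sim$jam_since > p$detach_persistence))) {
      sim <- finish_detach(sim)
    }
  } else if (sim$mode == "free") {
    cap <- free_cap_deg(p)
    if (all(sim$bends[2:(sim$n - 1L)] >= cap - 1e-9)) sim$done <- TRUE
  }

  if (sim$time >= p$max_time - 1e-9) {
    if (!sim$done && sim$mode == "hold") sim <- finish_detach(sim)
    sim$done <- TRUE
  }
  sim <- record_frame(sim, pos)
  sim
}

#' Simulate one coiling trial
#'
#' Initializes a straight tendril with the support tangent at
#' `contact_position` of its length (the support axis at right angles to the
#' tendril), then runs the two-rule coiling program until the wrap closes
#' around the support, the tendril detaches, or `max_time` is reached.
#' Deterministic given `params$seed` (and fully deterministic when
#' `jitter_sd = 0`).
#'
#' @param length Tendril length in mm.
#' @param support_diameter Support diameter in mm, or `NULL` to simulate
#'   stimulated free coiling with no support (the tendril relaxes to its
#'   intrinsic free-coil curvature).
#' @param params A `model_params` object.
#' @param contact_position Contact point as a fraction of tendril length from
#'   the root. Default 0.5 (middle of the tendril).
#' @return An object of class `tendril_trajectory`: per-frame times and node
#'   positions, the contact-node history, the event log, and summary fields
#'   (`total_wrap` is the total intrinsic wrap, the sum of joint bends, in
#'   degrees).
#' @export
simulate_coiling <- function(length, support_diameter = NULL,
                             params = model_params(),
                             contact_position = 0.5) {
  validate_model_params(params)
  if (!is.null(support_diameter) &&
      (!is.finite(support_diameter) || support_diameter <= 0)) {
    stop("support_diameter must be > 0 mm (or NULL for free coiling)",
         call. = FALSE)
  }
  if (!is.finite(length) || length <= 2 * params$ds) {
    stop("length must be > 2 * ds mm", call. = FALSE)
  }
  if (contact_position <= 0 || contact_position >= 1) {
    stop("contact_position must be in (0, 1)", call. = FALSE)
  }

  has_rng <- exists(".Random.seed", envir = globalenv())
  if (has_rng) old_seed <- get(".Random.seed", envir = globalenv())
  set.seed(params$seed)
  on.exit({
    if (has_rng) assign(".Random.seed", old_seed, envir = globalenv())
  })

  sim <- init_sim(length, support_diameter, params, contact_position)
  placed <- sim_positions(sim)
  sim <- record_frame(sim, placed$pos)
  nstep <- ceiling(params$max_time / params$dt)
  for (i in seq_len(nstep)) {
    if (sim$done) break
    sim <- sim_step(sim, params$dt)
  }

  ev <- if (length(sim$events) > 0L) {
    data.frame(time = vapply(sim$events, `[[`, numeric(1), "time"),
               event = vapply(sim$events, `[[`, character(1), "event"),
               node = vapply(sim$events, `[[`, integer(1), "node"))
  } else {
    data.frame(time = numeric(0), event = character(0), node = integer(0))
  }

  structure(
    list(times = sim$times, frames = sim$frames,
         contact = sim$contact_hist, events = ev,
         total_wrap = sum(sim$bends),
         bends = sim$bends,
         wrap_closed = sim$wrap_closed, tip_reached = sim$tip_reached,
         clip = sim$clip, detach_time = sim$detach_time,
         length = sim$L, ds = sim$ds, n = sim$n,
         support_diameter = support_diameter,
         contact_position = contact_position, params = params),
    class = "tendril_trajectory"
  )
}

#' @export
print.tendril_trajectory <- function(x, ...) {
  cat(sprintf("Coiling trial: tendril %.0f mm, support %s mm\n", x$length,
              if (is.null(x$support_diameter)) "none" else
                format(x$support_diameter)))
  cat(sprintf("  %d frames over %.1f min, total wrap %.1f deg\n",
              length(x$times), max(x$times), x$total_wrap))
  cat(sprintf("  events: %s\n", paste(unique(x$events$event), collapse = ", ")))
  invisible(x)
}

#' Advance a tendril state by one model time step
#'
#' Functional single-step interface around the simulation engine: applies the
#' coiling program (bend uptake around the active contact, contact migration
#' and liftoff per the two rules, seeded jitter) and returns the updated
#' state. With no contact and no prior stimulus the intrinsic bends are
#' unchanged (no stimulus, no coiling). Episode bookkeeping is carried in the
#' `"sim"` attribute of the returned state, so repeated calls continue the
#' same trial.
#'
#' @param state A `tendril_state` (as from [tendril_state()], or a previous
#'   `coil_step()` result).
#' @param support A `coil_support`.
#' @param params A `model_params` object.
#' @param dt Time step in minutes (> 0).
#' @return The updated `tendril_state`; `active_contact` holds the current
#'   contact node and the `"events"` attribute the events of this step.
#' @export
coil_step <- function(state, support, params = model_params(), dt = params$dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  sim <- attr(state, "sim")
  if (is.null(sim)) {
    n <- nrow(state$nodes)
    sim <- list(params = params, n = n, ds = state$ds,
                L = (n - 1L) * state$ds, bends = state$joint_bend,
                time = 0, events = list(), clip = FALSE,
                sway_streak = 0L, done = FALSE,
                wrap_closed = FALSE, tip_reached = FALSE,
                detach_time = NA_real_, wrap_arc = 0, episode_acc = 0,
                secondary_wrap = 0, laid_root = 0, jam_since = NA_real_,
                detached = FALSE,
                times = numeric(0), frames = list(),
                contact_hist = integer(0), support = support)
    c0 <- detect_contact(state, support, params$contact_tol)
    if (is.na(c0)) {
      sim$anchor <- NA_integer_
      sim$mode <- "idle"
      sim$stim0 <- NA_integer_
      sim$prev_contact <- NA_integer_
      sim$front <- NA_integer_
      sim$spread <- list(root_next = 1L, tip_next = n, root_on = FALSE,
                         tip_on = FALSE)
    } else {
      sim$anchor <- c0
      sim$stim0 <- c0
      sim$prev_contact <- c0
      sim$front <- c0
      sim$spread <- list(root_next = c0 - 1L, tip_next = c0 + 1L,
                         root_on = FALSE, tip_on = FALSE)
      sim$mode <- if (maintained_contact(params, support$diameter)) "curl"
                  else "advance"
      if (sim$mode == "curl") {
        k <- max(1L, ceiling(params$contact_window / params$ds))
        sim$window <- intersect(seq.int(c0, c0 + k - 1L), 2:(n - 1L))
        sim$window_cap <- params$theta_min / k
      }
      sim <- add_event(sim, "initial_contact", c0)
    }
  }
  n_events0 <- length(sim$events)
  if (sim$mode == "idle") {
    # no stimulus, no coiling: intrinsic bends unchanged
    sim$time <- sim$time + dt
    body <- body_chain(sim$bends, sim$ds)
    sim <- record_frame(sim, body$pos)
  } else {
    sim <- sim_step(sim, dt)
  }
  pos <- sim$frames[[length(sim$frames)]]
  out <- structure(
    list(nodes = cbind(pos, 0), ds = sim$ds, joint_bend = sim$bends,
         length = sim$L,
         active_contact = sim$contact_hist[length(sim$contact_hist)]),
    class = "tendril_state"
  )
  attr(out, "sim") <- sim
  attr(out, "events") <- sim$events[seq.int(n_events0 + 1L,
                                            length.out = length(sim$events) -
                                              n_events0)]
  out
}
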