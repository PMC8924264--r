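# shared fixtures: random rigid motions and exact circle samples

random_rotation3 <- function() {
  # QR of a Gaussian matrix gives a uniform random orthogonal matrix
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(pts, rot, shift, scale = 1) {
  sweep(scale * (pts %*% t(rot)), 2L, shift, `+`)
}

# points at given surface angles on a circle of radius r in the plane
# spanned by (e1, e2) about `center`
circle_points <- function(angles, r, center = c(0, 0, 0),
                          e1 = c(1, 0, 0), e2 = c(0, 1, 0)) {
  t(vapply(angles, function(a) center + r * cos(a) * e1 + r * sin(a) * e2,
           numeric(3)))
}

# worst penetration depth (negative = inside) and worst spacing error over
# all frames of a simulated trajectory
trajectory_physics <- function(traj) {
  sup <- coil_support(traj$support_diameter,
                      c(traj$contact_position * traj$length,
                        traj$support_diameter / 2, 0))
  worst_pen <- 0
  worst_seg <- 0
  for (f in traj$frames) {
    worst_pen <- min(worst_pen, min(tendrilcoil:::node_clearance(f, sup)))
    seg <- sqrt(rowSums((f[-1, , drop = FALSE] -
                           f[-nrow(f), , drop = FALSE])^2))
    worst_seg <- max(worst_seg, max(abs(seg - traj$ds)))
  }
  list(penetration = worst_pen, spacing = worst_seg)
}
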