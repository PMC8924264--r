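#' Pure geometric primitives for tendril curves and marker tracks
#'
#' All lengths are in millimetres and all angles in degrees throughout the
#' package. Points are length-3 numeric vectors (x, y, z); planar simulation
#' output uses z = 0.
#'
#' @name geometry
#' @keywords internal
NULL

.DEG <- 180 / pi

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) == 2L) p <- c(p, 0)
  if (length(p) != 3L || !all(is.finite(p))) {
    stop(sprintf("%s must be a finite (x, y, z) coordinate", what), call. = FALSE)
  }
  p
}

#' Bending angle at a marker
#'
#' Interior angle at vertex `p` between the rays `p -> p_prev` and
#' `p -> p_next`, in degrees. A value of 180 means the three markers are
#' collinear (locally straight tendril); smaller values mean a sharper bend.
#'
#' @param p_prev,p,p_next Numeric (x, y, z) coordinates in mm. Planar input
#'   (x, y) is accepted and padded with z = 0.
#' @return Angle in degrees, in \[0, 180\].
#' @examples
#' bending_angle(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)) # 180: straight
#' bending_angle(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0))  # 90
#' @export
bending_angle <- function(p_prev, p, p_next) {
  p_prev <- as_point3(p_prev, "p_prev")
  p <- as_point3(p, "p")
  p_next <- as_point3(p_next, "p_next")
  u <- p_prev - p
  v <- p_next - p
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu <= 1e-9 || nv <= 1e-9) {
    stop("degenerate geometry: a neighbour coincides with the vertex marker",
         call. = FALSE)
  }
  # atan2 of (||cross||, dot) is numerically stable near 0 and 180 degrees
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v)) * .DEG
}

#' Coiling angle at the contact marker
#'
#' Defined as 180 degrees minus the bending angle at the contact marker, so a
#' straight tendril scores 0 and the value grows as the tendril coils. This is
#' the per-frame quantity whose time course rises to the minimum coiling angle
#' during the rapid coiling stage and then plateaus.
#'
#' @param track_frame List (or 3-column matrix) of marker coordinates for one
#'   frame, root-most marker first.
#' @param contact_index Index (1-based) of the contact marker; must have a
#'   neighbour on each side.
#' @return Coiling angle in degrees, in \[0, 180\].
#' @export
coiling_angle_at <- function(track_frame, contact_index) {
  if (is.matrix(track_frame)) {
    track_frame <- lapply(seq_len(nrow(track_frame)), function(i) track_frame[i, ])
  }
  m <- length(track_frame)
  if (contact_index <= 1L || contact_index >= m) {
    stop("contact_index must have a neighbour marker on each side", call. = FALSE)
  }
  180 - bending_angle(track_frame[[contact_index - 1L]],
                      track_frame[[contact_index]],
                      track_frame[[contact_index + 1L]])
}

#' Fit a circle to 3D points
#'
#' Fits a total-least-squares plane through the points (via SVD of the
#' centred coordinates), projects the points onto that plane, runs a Pratt
#' algebraic circle fit in plane coordinates, and refines it with one
#' Gauss-Newton pass on the geometric (orthogonal) distances.
#'
#' @param points An n x 3 matrix or a list of (x, y, z) points, n >= 3.
#' @param collinear_tol Scale-free degeneracy tolerance: the fit aborts when
#'   the second-largest singular value of the centred coordinates is below
#'   `collinear_tol` times the largest.
#' @return An object of class `circle_fit`: a list with `center` (x, y, z),
#'   `diameter` (mm), `plane_normal` (unit vector), and `rms_residual` (mm,
#'   root-mean-square distance of the projected points to the fitted circle).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' pts <- cbind(10.2 * cos(th), 10.2 * sin(th), 0)
#' fit_circle_3d(pts)$diameter # 20.4
#' @export
fit_circle_3d <- function(points, collinear_tol = 1e-6) {
  if (is.list(points)) points <- do.call(rbind, lapply(points, as_point3))
  points <- as.matrix(points)
  if (ncol(points) == 2L) points <- cbind(points, 0)
  if (nrow(points) < 3L) {
    stop("degenerate geometry: need at least 3 points for a circle fit",
         call. = FALSE)
  }
  if (!all(is.finite(points))) stop("non-finite coordinates", call. = FALSE)

  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  sv <- svd(x)
  if (sv$d[2] < collinear_tol * sv$d[1]) {
    stop("degenerate geometry: points are (near-)collinear, no circle fit",
         call. = FALSE)
  }
  # plane basis = first two right-singular vectors; normal = third
  e1 <- sv$v[, 1]
  e2 <- sv$v[, 2]
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  uv <- cbind(x %*% e1, x %*% e2)

  ab <- pratt_circle(uv)
  ab <- gauss_newton_circle(uv, ab)
  c2 <- ab[1:2]
  r <- ab[3]
  if (!is.finite(r) || r < 1e-9) {
    stop("degenerate geometry: fitted circle radius is (near) zero", call. = FALSE)
  }
  d <- sqrt((uv[, 1] - c2[1])^2 + (uv[, 2] - c2[2])^2) - r
  center3 <- ctr + c2[1] * e1 + c2[2] * e2
  structure(
    list(center = as.numeric(center3),
         diameter = 2 * r,
         plane_normal = as.numeric(normal),
         rms_residual = sqrt(mean(d^2))),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("Circle fit: diameter %.3f mm, rms residual %.4g mm\n",
              x$diameter, x$rms_residual))
  cat(sprintf("  center (%.3f, %.3f, %.3f), plane normal (%.3f, %.3f, %.3f)\n",
              x$center[1], x$center[2], x$center[3],
              x$plane_normal[1], x$plane_normal[2], x$plane_normal[3]))
  invisible(x)
}

# Pratt algebraic circle fit in 2D plane coordinates.
# Solves the generalized eigenproblem for A(x^2+y^2) + Bx + Cy + D = 0 with
# the Pratt constraint B^2 + C^2 - 4AD = 1; robust to arcs far from a full
# circle, which is what marker subsets on a partial coil look like.
pratt_circle <- function(uv) {
  z <- uv[, 1]^2 + uv[, 2]^2
  M <- cbind(z, uv[, 1], uv[, 2], 1)
  S <- crossprod(M) / nrow(uv)
  Bc <- matrix(c(0, 0, 0, -2,
                 0, 1, 0, 0,
                 0, 0, 1, 0,
                 -2, 0, 0, 0), 4, 4, byrow = TRUE)
  eg <- eigen(solve(Bc, S))
  ev <- Re(eg$values)
  # the Pratt solution is the eigenvector of the smallest non-negative
  # eigenvalue; exact circle data makes it (numerically) zero
  ok <- which(ev > -1e-9 * max(abs(ev)))
  k <- ok[which.min(ev[ok])]
  v <- Re(eg$vectors[, k])
  A <- v[1]; B <- v[2]; C <- v[3]; D <- v[4]
  if (abs(A) < 1e-14) {
    stop("degenerate geometry: algebraic fit collapsed to a line", call. = FALSE)
  }
  cx <- -B / (2 * A)
  cy <- -C / (2 * A)
  r2 <- (B^2 + C^2 - 4 * A * D) / (4 * A^2)
  c(cx, cy, sqrt(max(r2, 0)))
}

# One Gauss-Newton pass on geometric distance sum((|p - c| - r)^2).
gauss_newton_circle <- function(uv, ab) {
  cx <- ab[1]; cy <- ab[2]; r <- ab[3]
  dx <- uv[, 1] - cx
  dy <- uv[, 2] - cy
  di <- sqrt(dx^2 + dy^2)
  di[di < 1e-12] <- 1e-12
  J <- cbind(-dx / di, -dy / di, -1)
  res <- di - r
  step <- tryCatch(qr.solve(J, -res), error = function(e) c(0, 0, 0))
  out <- ab + step
  # reject a pathological step (can only help, never replace, the Pratt fit)
  if (!all(is.finite(out)) || out[3] <= 0) ab else out
}

#' Resample a polyline at fixed arc-length intervals
#'
#' Returns points at arc-length multiples of `ds` along the polyline, using
#' linear interpolation between input vertices. The first input point is
#' always included. Used to place virtual markers at fixed intervals on
#' simulated tendril curves.
#'
#' @param points An n x 3 matrix (or list of points) tracing the polyline.
#' @param ds Arc-length spacing in mm, > 0.
#' @return A matrix of resampled points, one row per marker.
#' @export
resample_polyline <- function(points, ds) {
  if (is.list(points)) points <- do.call(rbind, lapply(points, as_point3))
  points <- as.matrix(points)
  if (ncol(points) == 2L) points <- cbind(points, 0)
  if (!all(is.finite(points))) stop("non-finite coordinates in polyline", call. = FALSE)
  if (!is.finite(ds) || ds <= 0) stop("ds must be > 0", call. = FALSE)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  targets <- seq(0, total, by = ds)
  out <- matrix(NA_real_, length(targets), 3)
  for (i in seq_along(targets)) {
    t <- targets[i]
    j <- findInterval(t, s, rightmost.closed = TRUE)
    j <- min(max(j, 1L), nrow(points) - 1L)
    w <- if (seg[j] > 0) (t - s[j]) / seg[j] else 0
    out[i, ] <- points[j, ] + w * (points[j + 1L, ] - points[j, ])
  }
  out
}
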