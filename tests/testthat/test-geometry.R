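test_that("bending angle matches its printed definition on canonical marker triples", {
  # collinear equally spaced markers: locally straight tendril
  expect_identical(bending_angle(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)), 180)
  expect_equal(bending_angle(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0)), 90)
  # three consecutive markers at 5 mm arc spacing on a circle of radius
  # 10.2 mm: interior angle is 180 - (180/pi) * (5 / 10.2)
  r <- 10.2
  dth <- 5 / r
  pts <- circle_points(c(-dth, 0, dth), r)
  expect_equal(bending_angle(pts[1, ], pts[2, ], pts[3, ]),
               180 - (180 / pi) * (5 / 10.2), tolerance = 1e-9)
  expect_error(bending_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "degenerate")
})

test_that("bending angle is invariant under rigid motion and scaling, and symmetric", {
  set.seed(42)
  for (i in 1:25) {
    pts <- matrix(rnorm(9, sd = 10), 3, 3)
    base <- bending_angle(pts[1, ], pts[2, ], pts[3, ])
    rot <- random_rotation3()
    shift <- rnorm(3, sd = 50)
    scale <- runif(1, 0.1, 10)
    moved <- apply_rigid(pts, rot, shift, scale)
    expect_equal(bending_angle(moved[1, ], moved[2, ], moved[3, ]), base,
                 tolerance = 1e-9)
    expect_equal(bending_angle(pts[3, ], pts[2, ], pts[1, ]), base,
                 tolerance = 1e-12)
  }
})

test_that("coiling angle is the straight-line complement of the bending angle", {
  straight <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0), c(15, 0, 0))
  expect_equal(coiling_angle_at(straight, 2), 0)
  bent <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0))
  expect_equal(coiling_angle_at(bent, 2), 90)
  expect_error(coiling_angle_at(straight, 1), "neighbour")
  expect_error(coiling_angle_at(straight, 4), "neighbour")
})

test_that("circle fitting recovers exact circles in arbitrary orientation", {
  # planar reference case at the thin-rod stop-stage diameter
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  fit <- fit_circle_3d(circle_points(th, 10.2))
  expect_equal(fit$diameter, 20.4, tolerance = 1e-6)
  expect_lt(fit$rms_residual, 1e-9)
  expect_equal(sum(fit$plane_normal^2), 1, tolerance = 1e-9)

  set.seed(7)
  for (i in 1:20) {
    r <- runif(1, 2, 50)
    rot <- random_rotation3()
    ctr <- rnorm(3, sd = 30)
    ang <- sort(runif(8, 0, 2 * pi))
    pts <- apply_rigid(circle_points(ang, r), rot, ctr)
    fit <- fit_circle_3d(pts)
    expect_equal(fit$diameter, 2 * r, tolerance = 1e-6 * 2 * r)
    expect_equal(fit$center, as.numeric(ctr), tolerance = 1e-5)
  }
})

test_that("circle fitting rejects degenerate input and tolerates marker noise", {
  expect_error(fit_circle_3d(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
  expect_error(fit_circle_3d(rbind(c(0, 0, 0), c(1, 0, 0))), "at least 3")
  # 12 noisy points (sigma = 0.1 mm) on the thick-rod stop-stage circle:
  # diameter recovered within 2 percent (worst case over a 100-seed pilot
  # was about 1 percent)
  set.seed(3)
  th <- sort(runif(12, 0, 2 * pi))
  pts <- circle_points(th, 8.05) + matrix(rnorm(36, 0, 0.1), 12, 3)
  expect_equal(fit_circle_3d(pts)$diameter, 16.1, tolerance = 0.02 * 16.1)
})

test_that("polyline resampling places markers at exact arc-length multiples", {
  out <- resample_polyline(rbind(c(0, 0, 0), c(10, 0, 0)), 5)
  expect_equal(out, rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)))
  # ds longer than the whole polyline: single sample at the start
  short <- resample_polyline(rbind(c(0, 0, 0), c(3, 0, 0)), 5)
  expect_equal(short, rbind(c(0, 0, 0)))
  # quarter circle of radius 10, finely discretized: the marker at half the
  # arc length lands on the analytic arc midpoint
  th <- seq(0, pi / 2, length.out = 1001)
  arc <- cbind(10 * cos(th), 10 * sin(th), 0)
  ds <- pi * 10 / 2 / 2
  out <- resample_polyline(arc, ds)
  expect_equal(out[2, ], c(10 * cos(pi / 4), 10 * sin(pi / 4), 0),
               tolerance = 1e-3)
  # spacing law on a random wiggly polyline
  set.seed(5)
  poly <- apply(matrix(rnorm(3 * 200, sd = 0.4), ncol = 3), 2, cumsum)
  res <- resample_polyline(poly, 1.5)
  gaps <- sqrt(rowSums(diff(res)^2))
  expect_true(all(gaps <= 1.5 + 1e-6))
  expect_error(resample_polyline(rbind(c(0, 0, 0), c(NA, 0, 0)), 1),
               "non-finite")
  expect_error(resample_polyline(rbind(c(0, 0, 0), c(1, 0, 0)), -1), "ds")
})
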