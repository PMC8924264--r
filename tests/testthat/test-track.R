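test_that("bending series of a straight motionless track is exactly 180 everywhere", {
  frames <- replicate(5, cbind(seq(0, 50, 5), 0, 0), simplify = FALSE)
  track <- marker_track(frames, 0:4)
  bs <- bending_series(track)
  expect_identical(dim(bs), c(5L, 9L)) # T x (m - 2)
  expect_true(all(bs == 180))
})

test_that("bending series flags degenerate triples as missing instead of aborting", {
  f <- cbind(seq(0, 20, 5), 0, 0)
  f[3, ] <- f[2, ] # coincident markers
  track <- marker_track(list(f), 0)
  expect_warning(bs <- bending_series(track), "degenerate")
  expect_true(any(is.na(bs)))
  expect_true(all(bs[!is.na(bs)] >= 0 & bs[!is.na(bs)] <= 180))
})

test_that("wrap tracks show the inscribed-arc bending angle in the stop stage", {
  track <- gen_wrap_track("fig5_thin")
  bs <- bending_series(track)
  stopf <- bs[nrow(bs), ]
  # interior markers fully on the coil (the junction marker at the contact
  # carries only half the turn)
  coiled <- stopf[stopf < 160]
  expect_equal(unname(coiled), rep(180 - (180 / pi) * (5 / 10.2),
                                   length(coiled)), tolerance = 1e-6)
})

test_that("the coiling-angle series round-trips the free-coil generator", {
  track <- gen_free_coil_track()
  m <- nrow(track$frames[[1]])
  ca <- coiling_angle_series(track, ceiling(m / 2))
  expect_equal(ca$plateau, 25, tolerance = 1e-9)
  expect_true(all(diff(ca$series) >= -1e-9)) # monotone rise to the plateau
  # straight track: all zeros
  straight <- marker_track(replicate(6, cbind(seq(0, 30, 5), 0, 0),
                                     simplify = FALSE), 0:5)
  expect_true(all(coiling_angle_series(straight, 3)$series == 0))
})

test_that("stage segmentation finds the stop stage where the angle stops changing", {
  series <- c(0, 5, 10, 15, 20, rep(25, 7))
  seg <- segment_stages(series, stop_eps = 1, persistence = 3)
  expect_identical(seg$stop_window, c(6L, 12L))
  expect_identical(seg$transform_window[1], 1L)
  # constant series: no transform motion, the whole range is stop
  seg2 <- segment_stages(rep(10, 8))
  expect_null(seg2$transform_window)
  expect_identical(seg2$stop_window, c(1L, 8L))
  # strictly rising series: no stop stage at all
  seg3 <- segment_stages(seq(0, 55, 5))
  expect_null(seg3$stop_window)
  expect_error(segment_stages(c(1, 2)), "frames")
})

test_that("stage segmentation is idempotent and stable under appended quiet frames", {
  series <- c(0, 5, 10, 15, 20, rep(25, 7))
  seg <- segment_stages(series)
  seg_again <- segment_stages(series)
  expect_identical(seg, seg_again)
  longer <- segment_stages(c(series, rep(25, 5)))
  expect_identical(longer$stop_window[1], seg$stop_window[1])
})

test_that("stop-stage diameters of the shipped presets are recovered", {
  for (nm in c(fig5_thin = 20.4, fig6_thick = 16.1)) TRUE
  cases <- list(list("fig5_thin", 20.4), list("fig6_thick", 16.1))
  for (cs in cases) {
    track <- gen_wrap_track(cs[[1]])
    rep <- analyze_track(track)
    expect_equal(rep$stop_stage_diameter, cs[[2]], tolerance = 1e-3)
  }
  # noisy preset: within 2 percent (tolerance from a 100-seed pilot of the
  # circle fit at this noise level)
  p <- wrap_preset("fig6_thick")
  p$noise_sd <- 0.1
  p$seed <- 4L
  noisy <- gen_wrap_track(p)
  rep <- analyze_track(noisy)
  expect_equal(rep$stop_stage_diameter, 16.1, tolerance = 0.02 * 16.1)
})

test_that("stop-stage fitting demands usable geometry", {
  frames <- replicate(8, cbind(seq(0, 50, 5), 0, 0), simplify = FALSE)
  track <- marker_track(frames, 0:7)
  seg <- segment_stages(rep(0, 8))
  expect_error(stop_stage_diameter(track, seg, marker_subset = 3:7),
               "collinear")
  expect_error(stop_stage_diameter(track,
                                   structure(list(stop_window = NULL),
                                             class = "stage_segmentation")),
               "no stop stage")
})

test_that("marker-track CSV round-trips and reports malformed input precisely", {
  track <- gen_wrap_track("fig6_thick")
  tmp <- tempfile(fileext = ".csv")
  write_track_csv(track, tmp)
  back <- read_track_csv(tmp)
  expect_equal(back$frames, track$frames, tolerance = 1e-12)
  expect_equal(back$frame_times, track$frame_times)

  df <- read.csv(tmp)
  df$z_mm <- NULL
  bad <- tempfile(fileext = ".csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(read_track_csv(bad), "z_mm")
})

test_that("marker-track invariants are enforced at construction", {
  f <- cbind(seq(0, 20, 5), 0, 0)
  expect_error(marker_track(list(f, f[-1, ]), 0:1), "same marker count")
  expect_error(marker_track(list(f, f), c(1, 1)), "strictly increasing")
  expect_error(marker_track(list(f[1:2, ]), 0), "at least 3 markers")
})
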