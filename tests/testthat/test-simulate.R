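test_that("contact detection returns the root-most touching node", {
  st <- tendril_state(20, ds = 1)
  # support tangent at node 7 (x = 6 mm); a tight tolerance excludes the
  # neighbouring nodes, whose sagitta distance is ds^2 / (2 R) = 0.1 mm
  sup <- coil_support(10, c(6, 5, 0))
  expect_identical(detect_contact(st, sup, 0.05), 7L)
  # far support: no contact
  expect_identical(detect_contact(st, coil_support(10, c(6, 50, 0)), 0.2),
                   NA_integer_)
  # two nodes within tolerance (5 and 9): tie-break is root-most, matching
  # an exhaustive distance scan
  st2 <- tendril_state(20, ds = 1)
  sup2 <- coil_support(20, c(0, 0, 0))
  st2$nodes[, 2] <- 40 # far away
  st2$nodes[5, 1:2] <- c(10.1, 0)
  st2$nodes[9, 1:2] <- c(0, 10.15)
  d <- pmax(sqrt(rowSums(st2$nodes[, 1:2]^2)) - 10, 0)
  expect_identical(min(which(d <= 0.2)), 5L)
  expect_identical(detect_contact(st2, sup2, 0.2), 5L)
  # a penetrating node projects to the surface and counts as touching
  st2$nodes[3, 1:2] <- c(0, 5)
  expect_identical(detect_contact(st2, sup2, 0.2), 3L)
})

test_that("stepping keeps the contact fixed on thin supports and migrates it on thick ones", {
  p <- model_params()
  # thin support (below the bifurcation diameter): contact never moves
  st <- tendril_state(100)
  sup <- coil_support(10, c(50, 5, 0))
  contacts <- vapply(1:50, function(i) {
    st <<- coil_step(st, sup, p)
    st$active_contact
  }, integer(1))
  expect_true(all(contacts == contacts[1]))

  # thick support: contact index non-decreasing with at least one liftoff
  st2 <- tendril_state(100)
  sup2 <- coil_support(40, c(50, 20, 0))
  contacts2 <- vapply(1:60, function(i) {
    st2 <<- coil_step(st2, sup2, p)
    st2$active_contact
  }, integer(1))
  seen <- contacts2[!is.na(contacts2)]
  expect_true(all(diff(seen) >= 0))
  expect_gt(max(seen) - seen[1], 1)
  ev <- vapply(attr(st2, "sim")$events, `[[`, character(1), "event")
  expect_gte(sum(ev == "liftoff"), 1L)

  # no stimulus, no coiling
  st3 <- tendril_state(50)
  far <- coil_support(10, c(200, 100, 0))
  st3b <- coil_step(st3, far, p)
  expect_identical(st3b$joint_bend, numeric(51))
  expect_error(coil_step(st3, far, p, dt = 0), "dt")
})

test_that("simulated trials never penetrate the support and conserve segment lengths", {
  cells <- list(c(100, 10), c(60, 35), c(160, 20), c(160, 35))
  for (js in c(0, 15)) {
    for (cell in cells) {
      traj <- simulate_coiling(cell[1], cell[2],
                               model_params(jitter_sd = js, seed = 2))
      phys <- trajectory_physics(traj)
      expect_gt(phys$penetration, -1e-6)
      expect_lt(phys$spacing, 1e-6)
    }
  }
})

test_that("trials are bit-for-bit deterministic under a fixed seed", {
  p <- model_params(jitter_sd = 15, seed = 9)
  t1 <- simulate_coiling(120, 24, p)
  t2 <- simulate_coiling(120, 24, p)
  expect_identical(t1, t2)
  # a different seed changes the stochastic branch somewhere in the grid
  t3 <- simulate_coiling(120, 24, model_params(jitter_sd = 15, seed = 10))
  expect_identical(class(t3), "tendril_trajectory")
})

test_that("without a support the tendril converges to the free-coil curvature", {
  p <- model_params(max_time = 60)
  traj <- simulate_coiling(30, NULL, p)
  kappa <- traj$bends[2:(traj$n - 1)] * pi / 180 / traj$ds
  expect_true(all(abs(kappa - 2 / p$free_coil_diameter) <
                    0.01 * 2 / p$free_coil_diameter))
})

test_that("simulation inputs are validated", {
  expect_error(simulate_coiling(100, -5), "support_diameter")
  expect_error(simulate_coiling(100, 0), "support_diameter")
  expect_error(simulate_coiling(1, 10), "length")
  expect_error(simulate_coiling(100, 10, contact_position = 1.2),
               "contact_position")
  expect_error(model_params(theta_min = -1), "theta_min")
  expect_error(model_params(coiling_rate = 0), "coiling_rate")
})

test_that("the implied step-1 bifurcation diameter follows from the liftoff rule", {
  p <- model_params()
  phi_star <- bifurcation_diameter(p)
  expect_equal(phi_star, 2 * p$contact_window / (p$theta_min * pi / 180))
  expect_true(tendrilcoil:::maintained_contact(p, phi_star - 1e-6))
  expect_false(tendrilcoil:::maintained_contact(p, phi_star + 1e-3))
})
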