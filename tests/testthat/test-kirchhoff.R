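gc_ref <- hypergeom_threshold()

test_that("tangent-angle fields map to unit-arclength polylines", {
  xy <- to_xy(rep(0, 8))
  expect_equal(xy[, 1], seq(0, 1, by = 1 / 8))
  expect_equal(xy[, 2], rep(0, 9))
  xy <- to_xy(rep(pi / 2, 8))
  expect_equal(xy[, 2], seq(0, 1, by = 1 / 8))
  expect_equal(xy[, 1], rep(0, 9), tolerance = 1e-15)
  # random smooth field: spacing and total arclength exact
  phi <- 0.8 * sin(2 * pi * glidebuckle:::segment_midpoints(32))
  xy <- to_xy(phi)
  seg <- sqrt(rowSums(diff(xy)^2))
  expect_equal(seg, rep(1 / 32, 32), tolerance = 1e-12)
  expect_equal(sum(seg), 1, tolerance = 1e-9)
})

test_that("subcritical activity decays, supercritical grows to 90 degrees", {
  sub <- evolve(0.5 * gc_ref, n = 32)
  expect_true(sub$decayed)
  expect_null(sub$snapshots)
  expect_lt(sub$rate, 0)

  sup <- evolve(2 * gc_ref, n = 32)
  expect_false(sup$decayed)
  expect_equal(nrow(sup$snapshots), 64)
  expect_equal(abs(tail(sup$snapshots$head_angle, 1)), pi / 2,
    tolerance = 1e-4
  )
  expect_true(all(diff(sup$snapshots$t_scaled) > 0))
  # head pinned by construction at every snapshot
  heads <- t(vapply(sup$snapshots$xy, function(m) m[1, ], numeric(2)))
  expect_lt(max(abs(heads)), 1e-6)
})

test_that("early-time growth matches the linearized eigenvalue", {
  ev <- evolve(2 * gc_ref, n = 48, init_amplitude = 1e-3)
  small <- abs(ev$snapshots$head_angle) < 0.05
  small[1] <- FALSE # t = 0 excluded from the log-linear fit
  expect_gt(sum(small), 5)
  fit <- lm(log(abs(head_angle)) ~ t_scaled,
    data = ev$snapshots[small, ]
  )
  expect_equal(unname(coef(fit)[2]), ev$rate, tolerance = 0.05)
})

test_that("stored snapshots keep torque-free ends", {
  ev <- evolve(2 * gc_ref, n = 64)
  n <- ev$n
  h <- 1 / n
  for (i in c(2, 32, 64)) {
    phi <- ev$snapshots$phi[[i]]
    # curvature at the boundary under the solver's ghost-node convention
    kappa0 <- (phi[1] - phi[1]) / h
    kappaL <- (phi[n] - phi[n]) / h
    expect_identical(kappa0, 0)
    expect_identical(kappaL, 0)
    # extrapolated boundary curvature is small relative to the interior
    # maximum (discretization error of the continuum torque-free condition)
    kappa <- diff(phi) / h
    k0 <- 2 * kappa[1] - kappa[2]
    kL <- 2 * kappa[n - 1] - kappa[n - 2]
    expect_lt(abs(k0), 0.01 * max(abs(kappa)))
    expect_lt(abs(kL), 0.01 * max(abs(kappa)))
  }
})

test_that("grid refinement leaves the final contour unchanged within 1%", {
  e64 <- evolve(2 * gc_ref, n = 64)
  e128 <- evolve(2 * gc_ref, n = 128)
  a <- resample_contour(e64$snapshots$xy[[64]], 64)
  b <- resample_contour(e128$snapshots$xy[[64]], 64)
  rms <- sqrt(mean(rowSums((a - b)^2)))
  expect_lt(rms, 0.01) # in units of the contour length
})

test_that("growth/decay boundary agrees with the threshold within 2%", {
  lo <- 25
  hi <- 40
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    if (glidebuckle:::leading_mode(mid, 64)$rate > 0) hi <- mid else lo <- mid
  }
  expect_equal((lo + hi) / 2, gc_ref, tolerance = 0.02)
})

test_that("rotor frequency vanishes toward threshold and flips with the mode sign", {
  r_low <- measure_rotor_omega(1.1 * gc_ref, n = 32)
  r_high <- measure_rotor_omega(1.5 * gc_ref, n = 32)
  expect_true(r_low$converged)
  expect_true(r_high$converged)
  expect_lt(abs(r_low$omega), abs(r_high$omega))
  r_flip <- measure_rotor_omega(1.1 * gc_ref, n = 32,
    init_amplitude = -0.01
  )
  expect_equal(r_flip$omega, -r_low$omega, tolerance = 0.05)
  r_sub <- measure_rotor_omega(0.8 * gc_ref, n = 32)
  expect_false(r_sub$converged)
  expect_true(is.na(r_sub$omega))
})

test_that("profile library interpolates exactly at nodes and well between", {
  lib <- test_library()
  expect_true(all(diff(lib$gamma_grid) > 0))
  expect_true(all(lib$gamma_grid > gc_ref))

  # identity at a grid node / stored snapshot
  k <- 3
  mem <- lib$members[[k]]
  xy_interp <- library_contour(lib, lib$gamma_grid[k], mem$times[20])
  expect_equal(xy_interp, to_xy(mem$phi[20, ]), tolerance = 1e-12)

  # midway in gamma: compare against a direct evolution
  g_mid <- sqrt(lib$gamma_grid[3] * lib$gamma_grid[4])
  ev <- evolve(g_mid, n = lib$n)
  t_probe <- 0.6 * max(ev$snapshots$t_scaled)
  i <- which.min(abs(ev$snapshots$t_scaled - t_probe))
  direct <- ev$snapshots$xy[[i]]
  interp <- library_contour(lib, g_mid, ev$snapshots$t_scaled[i])
  rms <- sqrt(mean(rowSums((direct - interp)^2)))
  expect_lt(rms, 0.02)

  # outside the hull
  expect_null(library_phi(lib, lib$gamma_grid[1], 1e9))
  expect_error(library_time_range(lib, 0.5 * gc_ref), "outside")
  expect_error(build_profile_library(lc_ratio_min = 0.9), "lc_ratio_min")
})
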