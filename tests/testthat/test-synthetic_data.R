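test_that("event generation follows the logistic outcome model", {
  spec <- population_spec(truth = list(Lc_um = 161, dLc_um = 35))
  ev <- gen_events(spec, n_events = 388, seed = 1)
  expect_equal(nrow(ev), 388)
  expect_true(all(ev$buckled %in% 0:1))
  expect_true(all(ev$weight == 1 / ev$N_i))
  expect_identical(attr(ev, "truth")$Lc_um, 161)

  # determinism given seed
  expect_identical(ev, gen_events(spec, n_events = 388, seed = 1))

  # empirical buckling fraction near the median is about one half
  big <- gen_events(spec, n_events = 5000, seed = 2)
  near <- dplyr::filter(big, abs(length_um - 161) < 20)
  expect_equal(mean(near$buckled), 0.5, tolerance = 0.1)

  # marginal probability converges to the logistic pointwise
  huge <- gen_events(spec, n_events = 30000, seed = 3)
  for (L0 in c(100, 161, 250)) {
    sel <- dplyr::filter(huge, abs(length_um - L0) < 15)
    p_hat <- mean(sel$buckled)
    p_true <- plogis((L0 - 161) / 35)
    expect_equal(p_hat, p_true,
      tolerance = 4 * sqrt(p_true * (1 - p_true) / nrow(sel)) + 0.02
    )
  }
})

test_that("vanishing width gives a deterministic step at Lc", {
  spec <- population_spec(truth = list(Lc_um = 200, dLc_um = 1e-9))
  ev <- gen_events(spec, n_events = 500, seed = 4)
  expect_true(all(ev$buckled[ev$length_um > 200 + 1e-6] == 1))
  expect_true(all(ev$buckled[ev$length_um < 200 - 1e-6] == 0))
})

test_that("velocity coupling at fixed speed matches the length-only model", {
  B <- 1.4e-16
  eta <- 0.6
  spec_v <- population_spec(
    speed_dist = list(family = "uniform", min = 2, max = 2),
    truth = list(eta_nNs_um2 = eta, dLc_um = 35, B = B)
  )
  ev <- gen_events(spec_v, n_events = 4000, model = "velocity_coupled",
                   seed = 5)
  # implied fixed critical length
  Lc2 <- m_to_um(critical_length_velocity(B, nNs_per_um2_to_SI(eta), 2e-6))
  near <- dplyr::filter(ev, abs(length_um - Lc2) < 20)
  expect_equal(mean(near$buckled), 0.5, tolerance = 0.1)
})

test_that("length samples follow the requested family", {
  x <- gen_length_sample(n = 10000, seed = 6)
  expect_true(all(x > 0))
  s <- attr(x, "summary")
  # log-normal mode = exp(meanlog - sdlog^2)
  expect_equal(s$mode, 150 * exp(-0.36), tolerance = 0.15)
  expect_length(gen_length_sample(n = 0), 0)
  expect_error(
    gen_length_sample(list(family = "cauchy"), n = 10, seed = 1),
    "unknown"
  )
})

test_that("synthetic bending curves encode the target modulus", {
  curve <- gen_bending_curve(1.4e-16, noise_frac = 0, seed = 1)
  tr <- attr(curve, "truth")
  expect_equal(tr$slope_nN_um, 13.125, tolerance = 1e-6)
  sl <- fit_slope(curve$force_nN, curve$filament_deflection_um)
  expect_equal(sl$slope_nN_um, tr$slope_nN_um, tolerance = 1e-10)
  # doubling B doubles the slope
  tr2 <- attr(gen_bending_curve(2.8e-16, noise_frac = 0, seed = 1), "truth")
  expect_equal(tr2$slope_nN_um, 2 * tr$slope_nN_um)
  # pipette deflection consistent with Hooke's law
  expect_equal(
    pipette_force(curve$pipette_deflection_um, 9.5), curve$force_nN
  )
})

test_that("synthetic contour tracks are inextensible and seeded", {
  gc_ <- hypergeom_threshold()
  tr <- gen_contour_track(
    gamma = 3 * gc_, t0_s = 60, L_um = 150, noise_um = 0,
    n_frames = 5, n = 32, seed = 9
  )
  expect_equal(nrow(tr$frames), 5)
  for (xy in tr$frames$xy) {
    expect_equal(glidebuckle:::polyline_length(xy), 150, tolerance = 1.5e-3)
  }
  tr2 <- gen_contour_track(
    gamma = 3 * gc_, t0_s = 60, L_um = 150, noise_um = 0.4,
    n_frames = 5, n = 32, seed = 9
  )
  expect_identical(
    tr2$frames$xy,
    gen_contour_track(
      gamma = 3 * gc_, t0_s = 60, L_um = 150, noise_um = 0.4,
      n_frames = 5, n = 32, seed = 9
    )$frames$xy
  )
  # frame times beyond the stopping point are truncated with a warning:
  # reuse the default spacing (which spans the evolution with 5 frames)
  # but ask for 10 frames
  dt_fit <- tr$frames$t_s[2] - tr$frames$t_s[1]
  expect_warning(
    tr3 <- gen_contour_track(
      gamma = 3 * gc_, t0_s = 60, L_um = 150, noise_um = 0,
      n_frames = 10, frame_dt_s = dt_fit, n = 32, seed = 1
    ),
    "truncated"
  )
  expect_lt(nrow(tr3$frames), 10)
  expect_error(
    gen_contour_track(gamma = 0.5 * gc_, t0_s = 60, L_um = 150, n = 32),
    "subcritical"
  )
})
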