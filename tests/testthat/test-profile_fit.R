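test_that("arclength resampling preserves geometry", {
  seg <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  r <- resample_contour(seg, 64)
  expect_equal(nrow(r), 64)
  d <- sqrt(rowSums(diff(r)^2))
  expect_equal(d, rep(5 / 63, 63), tolerance = 1e-12)

  # idempotence on an already equally spaced polyline
  r2 <- resample_contour(r, 64)
  expect_equal(r2, r, tolerance = 1e-9)

  # semicircle arclength within 0.1% of pi * r
  th <- seq(0, pi, length.out = 256)
  semi <- cbind(10 * cos(th), 10 * sin(th))
  rs <- resample_contour(semi, 128)
  expect_equal(
    glidebuckle:::polyline_length(rs), pi * 10,
    tolerance = 1e-3
  )
  expect_error(resample_contour(matrix(1, 3, 2), 10), "degenerate")
})

test_that("a rigidly transformed library snapshot is recovered exactly", {
  lib <- test_library()
  k <- 4
  mem <- lib$members[[k]]
  i <- 40
  rot <- 0.3
  trans <- c(5, -7)
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  L_um <- 200
  frame <- sweep((to_xy(mem$phi[i, ]) * L_um) %*% t(R), 2, trans, "+")

  f <- fit_frame(frame, lib, L_um)
  expect_lt(f$residual_um2, 1e-6)
  expect_equal(f$gamma, lib$gamma_grid[k], tolerance = 1e-4)
  expect_equal(f$rotation, rot, tolerance = 1e-3)
  expect_equal(c(f$tx_um, f$ty_um), trans, tolerance = 0.1)
  expect_false(f$mirrored)
})

test_that("frame fits tolerate localization noise", {
  lib <- test_library()
  k <- 5
  mem <- lib$members[[k]]
  i <- 44
  L_um <- 200
  set.seed(31)
  frame <- to_xy(mem$phi[i, ]) * L_um +
    matrix(rnorm(2 * (lib$n + 1), 0, 0.5), ncol = 2)
  f <- fit_frame(frame, lib, L_um)
  expect_equal(f$gamma, lib$gamma_grid[k], tolerance = 0.15)
})

test_that("straight contours are flagged uninformative", {
  lib <- test_library()
  straight <- cbind(seq(0, 200, length.out = 64), 0)
  f <- fit_frame(straight, lib, 200)
  expect_true(f$uninformative)
})

test_that("global fit reaches machine-precision residual on noiseless tracks", {
  lib <- test_library()
  track <- library_track(lib)
  fit <- fit_global(track, lib)
  expect_lt(fit$residual_um2, 1e-9)
  expect_equal(fit$gamma, track$truth$gamma, tolerance = 1e-5)
  expect_equal(fit$t0_s, track$truth$t0_s, tolerance = 1e-4)
})

test_that("global fit recovers parameters from noisy solver tracks", {
  lib <- test_library()
  g_true <- sqrt(lib$gamma_grid[4] * lib$gamma_grid[5])
  track <- gen_contour_track(
    gamma = g_true, t0_s = 120, L_um = 200, noise_um = 0.3,
    n_frames = 8, rotation = -0.7, translation = c(3, 9),
    species_B = 1.4e-16, n = 32, seed = 8
  )
  fit <- fit_global(track, lib)
  expect_equal(fit$gamma, g_true, tolerance = 0.10)
  expect_equal(fit$t0_s, 120, tolerance = 0.10)
  # physical conversions: f = gamma B / L^3, eta = t0 B / L^4
  L_m <- um_to_m(200)
  expect_equal(fit$f_N_per_m, fit$gamma * 1.4e-16 / L_m^3)
  expect_equal(fit$eta_SI, fit$t0_s * 1.4e-16 / L_m^4)
})

test_that("relabeling frame times only shifts the fitted offset", {
  lib <- test_library()
  track <- library_track(lib, k = 3, t0_s = 50)
  set.seed(1)
  fit1 <- fit_global(track, lib, n_restarts = 1)
  shifted <- track
  shifted$frames$t_s <- track$frames$t_s + 13.5
  set.seed(1)
  fit2 <- fit_global(shifted, lib, n_restarts = 1)
  expect_equal(fit2$t_offset_s, fit1$t_offset_s + 13.5, tolerance = 1e-6)
  expect_equal(fit2$gamma, fit1$gamma, tolerance = 1e-6)
  expect_equal(fit2$t0_s, fit1$t0_s, tolerance = 1e-6)
})

test_that("derived forces are invariant under rigid motion of the data", {
  lib <- test_library()
  track <- library_track(lib, k = 4)
  set.seed(2)
  fit1 <- fit_global(track, lib, n_restarts = 1)
  rot <- -1.1
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  moved <- track
  moved$frames$xy <- lapply(
    track$frames$xy,
    function(m) sweep(m %*% t(R), 2, c(40, -15), "+")
  )
  set.seed(2)
  fit2 <- fit_global(moved, lib, n_restarts = 1)
  expect_equal(fit2$f_nN_per_um, fit1$f_nN_per_um, tolerance = 1e-6)
  expect_equal(fit2$eta_nNs_um2, fit1$eta_nNs_um2, tolerance = 1e-6)
})

test_that("global fit beats per-frame averages on noiseless tracks", {
  lib <- test_library()
  track <- library_track(lib, k = 5)
  fit <- fit_global(track, lib)
  pf <- fit$per_frame
  g_avg <- exp(mean(log(pf$gamma)))
  # residual of the joint optimum vs the averaged per-frame parameters
  frames_res <- lapply(track$frames$xy, resample_contour, n = 64)
  sl <- coef(lm(pf$t_scaled ~ track$frames$t_s))
  res_avg <- glidebuckle:::global_residual(
    lib, g_avg, 1 / sl[2], -sl[1] / sl[2], frames_res, track$frames$t_s,
    track$L_um, FALSE, 64
  )
  expect_lte(fit$residual_um2, res_avg + 1e-12)
})

test_that("bootstrap spread is near zero without noise and grows with it", {
  lib <- test_library()
  track0 <- library_track(lib, k = 4, n_frames = 8)
  b0 <- bootstrap_global(track0, lib, n_resamples = 6, seed = 3,
                         n_points = 48)
  iqr0 <- attr(b0$bootstrap, "iqr")
  expect_lt(iqr0[["gamma"]] / b0$gamma, 1e-4)

  g_true <- lib$gamma_grid[4]
  mk_noisy <- function(noise, seed) {
    tr <- library_track(lib, k = 4, n_frames = 8)
    set.seed(seed)
    tr$frames$xy <- lapply(tr$frames$xy, function(m) {
      m + matrix(rnorm(length(m), 0, noise), ncol = 2)
    })
    tr
  }
  b_small <- bootstrap_global(mk_noisy(0.1, 21), lib, n_resamples = 6,
                              seed = 4, n_points = 48)
  b_large <- bootstrap_global(mk_noisy(1.0, 22), lib, n_resamples = 6,
                              seed = 5, n_points = 48)
  expect_lt(
    attr(b_small$bootstrap, "iqr")[["gamma"]],
    attr(b_large$bootstrap, "iqr")[["gamma"]]
  )
  # resample settings recorded with the result
  expect_equal(attr(b0$bootstrap, "n_resamples"), 6)
  expect_equal(attr(b0$bootstrap, "subset_frac"), 0.5)
  # the coarse-bootstrap default matches the published procedure
  expect_equal(formals(bootstrap_global)$n_resamples, 20)
})
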