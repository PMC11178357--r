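test_that("hypergeometric series evaluates correctly at trivial arguments", {
  expect_equal(pfq(numeric(0), 2 / 3, 0), 1)
  expect_equal(pfq(1 / 3, c(2 / 3, 4 / 3), 0), 1)
  # exp(z) = 0F0... via recurrence against base R
  expect_equal(pfq(1, 1, -1.3), exp(-1.3), tolerance = 1e-13)
  expect_error(pfq(1, c(0, 2), 1), "non-positive")
})

test_that("threshold equation has its trivial root at k = 0", {
  # all pFq(...; 0) = 1 so the left side equals the right side exactly
  expect_equal(threshold_equation(0), 0)
})

test_that("hypergeometric route gives the buckling threshold", {
  k <- hypergeom_threshold()
  expect_gt(k, 1) # trivial root excluded by the bracket
  expect_equal(k, 30.5722, tolerance = 1e-3 / 30.5722)
  expect_equal(k, REF_HYPERGEOM_ROOT, tolerance = 1e-10)
  expect_lt(abs(threshold_equation(k)), 1e-8)
  # no root below the threshold: bracketing must fail there
  expect_error(
    hypergeom_threshold(interval = c(1, 5)),
    "no sign change"
  )
})

test_that("shooting solver reproduces the threshold for the pinned-free set", {
  cp <- linear_threshold_numeric("pinned_free_tangential")
  expect_s3_class(cp, "critical_point")
  expect_equal(cp$gamma_c, 30.5722, tolerance = 1e-3 / 30.5722)
  # two independent routes to the same constant
  expect_equal(cp$gamma_c, hypergeom_threshold(), tolerance = 1e-3 / 30)

  # null mode satisfies all three boundary conditions, normalized with
  # max |kappa| = 1 and kappa'(0) > 0
  mode <- cp$mode
  n <- nrow(mode)
  expect_lt(abs(mode$kappa[1]), 1e-6)
  expect_lt(abs(mode$kappa[n]), 1e-6)
  # all three conditions via the boundary system applied to the null vector
  M <- glidebuckle:::boundary_system(
    cp$gamma_c, boundary_conditions("pinned_free_tangential")
  )
  v <- svd(M)$v[, 3]
  expect_lt(max(abs(M %*% v)), 1e-6)
  expect_equal(max(abs(mode$kappa)), 1)
  expect_gt(mode$kappa[2] - mode$kappa[1], 0)
})

test_that("clamped-free gravity set gives the heavy-column constant", {
  cp <- linear_threshold_numeric("clamped_free_gravity")
  expect_equal(cp$gamma_c, 7.837, tolerance = 1e-2 / 7.837)
  expect_equal(cp$gamma_c, REF_HEAVY_COLUMN, tolerance = 1e-8)
  expect_identical(cp$omega, 0)
})

test_that("boundary determinant has a single sign change in (1, 50)", {
  bcs <- boundary_conditions("pinned_free_tangential")
  grid <- exp(seq(log(1), log(50), length.out = 80))
  dets <- vapply(
    grid, function(g) det(glidebuckle:::boundary_system(g, bcs)), numeric(1)
  )
  expect_equal(sum(diff(sign(dets)) != 0), 1)
})

test_that("critical length formula and its inverses are consistent", {
  Lc <- critical_length(B = 1.4e-16, f = 1.0e-3)
  expect_equal(m_to_um(Lc), 162.4, tolerance = 1e-3)

  # cube-root homogeneity
  expect_equal(
    critical_length(1.4e-16, 8e-3), critical_length(1.4e-16, 1e-3) / 2
  )
  # exact inverse pair over a parameter sweep
  for (B in c(1e-16, 1.4e-16, 3e-16)) {
    for (f in c(2e-4, 1e-3, 5e-3)) {
      Lc <- critical_length(B, f)
      expect_equal(force_from_critical_length(B, Lc), f, tolerance = 1e-12)
    }
  }
  expect_error(critical_length(1e-16, 0), "> 0")
  expect_error(critical_length(-1, 1e-3), "> 0")
})

test_that("force from the printed species medians is about 1 nN/um", {
  f_ol <- force_from_critical_length(1.4e-16, um_to_m(161))
  expect_equal(N_per_m_to_nN_per_um(f_ol), 1.026, tolerance = 1e-3)
  f_ka <- force_from_critical_length(1.0e-16, um_to_m(148))
  expect_equal(N_per_m_to_nN_per_um(f_ka), 0.943, tolerance = 1e-3)
  # linear in B at fixed Lc
  expect_equal(
    force_from_critical_length(2.8e-16, um_to_m(161)), 2 * f_ol
  )
  expect_error(force_from_critical_length(1e-16, -1), "> 0")
})

test_that("velocity-dependent critical length matches the substitution f = eta v0", {
  B <- 1.4e-16
  eta <- 600 # SI, = 0.6 nN s um^-2
  v0 <- 2e-6
  Lc <- critical_length_velocity(B, eta, v0)
  expect_equal(m_to_um(Lc), 152.8, tolerance = 1e-3)
  expect_equal(Lc, critical_length(B, eta * v0), tolerance = 1e-12)
  expect_equal(
    critical_length_velocity(B, eta, 8 * v0), Lc / 2,
    tolerance = 1e-12
  )
  expect_error(critical_length_velocity(B, 0, v0), "> 0")
})

test_that("unit conversions and printed formatting round-trip", {
  expect_equal(nN_per_um_to_N_per_m(1), 1e-3)
  expect_equal(N_per_m_to_nN_per_um(nN_per_um_to_N_per_m(0.37)), 0.37)
  expect_equal(nNs_per_um2_to_SI(0.6), 600)
  expect_equal(um_to_m(m_to_um(1.23e-5)), 1.23e-5)
  expect_equal(parse_Jm(format_Jm(1.4e-16)), 1.4e-16)
  p <- elastica_params(B = 1.4e-16, f = 1e-3, eta = 600, L = 2e-4)
  expect_equal(activity_coefficient(p), 2e-4^3 * 1e-3 / 1.4e-16)
  expect_error(elastica_params(B = -1), "B must be")
})
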