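# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# small profile library reused across the profile-fit tests (moderate grid,
# coarse discretization keeps the build at a few seconds)
test_library <- function() {
  if (is.null(fixture_env$lib)) {
    fixture_env$lib <- build_profile_library(
      lc_ratio_min = 1.15, lc_ratio_max = 2.6, count = 7, n = 32,
      n_snapshots = 48
    )
  }
  fixture_env$lib
}

# a noiseless track assembled directly from library snapshots of member k,
# so a perfect fit exists inside the library by construction
library_track <- function(lib, k = 4, n_frames = 6, L_um = 200,
                          rotation = 0.3, translation = c(5, -7),
                          t0_s = 77) {
  member <- lib$members[[k]]
  idx <- round(seq(
    which.max(member$times > 0.4 * max(member$times)),
    lib$n_snapshots,
    length.out = n_frames
  ))
  R <- matrix(
    c(cos(rotation), sin(rotation), -sin(rotation), cos(rotation)), 2, 2
  )
  xy <- lapply(idx, function(i) {
    sweep((to_xy(member$phi[i, ]) * L_um) %*% t(R), 2, translation, "+")
  })
  structure(
    list(
      frames = tibble::tibble(
        frame = seq_along(idx), t_s = member$times[idx] * t0_s, xy = xy
      ),
      L_um = L_um, species_B = 1.4e-16,
      valid = rep(TRUE, length(idx)),
      truth = list(
        gamma = lib$gamma_grid[k], t0_s = t0_s, rotation = rotation,
        translation = translation
      )
    ),
    class = "contour_track"
  )
}

# high-precision reference constants (independent arbitrary-precision
# evaluation, frozen)
REF_HYPERGEOM_ROOT <- 30.57218527764168
REF_HEAVY_COLUMN <- 7.837347438943484
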