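# Synthetic-data generators.
#
# Every input the analysis pipeline consumes can be generated here with the
# statistical structure the analysis assumes: collision-event tables with
# repeated observations per individual and Bernoulli outcomes from the
# logistic model; contour tracks sampled from the Kirchhoff solver with
# localization noise; linear force-deflection curves with sensor noise.
# Ground truth is embedded in an attribute so recovery tests are
# self-contained, and every generator is deterministic given its seed.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Specification of a synthetic filament population
#'
#' Collects the sampling distributions for a population of colliding
#' filaments: contour lengths, free-gliding speeds, number of repeat
#' observations per individual, and the mechanical ground truth used to
#' draw outcomes.
#'
#' Defaults emulate the study conditions: lengths uniform on 30-600 um
#' (broad coverage around the threshold), speeds uniform on 1-3 um/s (the
#' characteristic observed range), repeats 1 + geometric with mean 2
#' observations per individual.
#'
#' @param length_dist list: `family` ("uniform" or "lognormal") plus
#'   parameters (`min`/`max` in um, or `meanlog`/`sdlog`).
#' @param speed_dist list: `family` "uniform", `min`/`max` in um/s.
#' @param repeats_dist list: `family` "geometric", `mean` expected
#'   observations per individual (>= 1).
#' @param truth list of generating parameters. For the length-only outcome
#'   model: `Lc_um`, `dLc_um`. For the velocity-coupled model: `eta_nNs_um2`,
#'   `dLc_um`, `B` (N m^2).
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(length_dist = list(family = "uniform",
                                               min = 30, max = 600),
                            speed_dist = list(family = "uniform",
                                              min = 1, max = 3),
                            repeats_dist = list(family = "geometric",
                                                mean = 2),
                            truth = list(Lc_um = 161, dLc_um = 35)) {
  stopifnot(repeats_dist$mean >= 1)
  structure(
    list(
      length_dist = length_dist, speed_dist = speed_dist,
      repeats_dist = repeats_dist, truth = truth
    ),
    class = "population_spec"
  )
}

draw_lengths <- function(dist, n) {
  switch(dist$family,
    uniform = runif(n, dist$min, dist$max),
    lognormal = rlnorm(n, dist$meanlog, dist$sdlog),
    abort(paste("unknown length distribution family:", dist$family))
  )
}

#' Generate a synthetic collision-event table
#'
#' Samples individuals (one length each) observed a geometric-distributed
#' number of times until `n_events` events are accumulated, then draws each
#' outcome Bernoulli(p) with p from the logistic model: length-only
#' p = sig((L - Lc)/dLc), or velocity-coupled with
#' Lc(v0) = (alpha v0)^(-1/3), alpha = eta / (k B). Weights 1/N_i are
#' assigned, and the generating truth is stored in `attr(, "truth")`.
#'
#' @param spec a [population_spec()].
#' @param n_events total number of events.
#' @param model `"length_only"` or `"velocity_coupled"`.
#' @param seed integer seed (restored on exit).
#' @return tibble with columns `individual_id`, `length_um`, `speed_um_s`,
#'   `buckled`, `N_i`, `weight`.
#' @examples
#' ev <- gen_events(population_spec(), n_events = 388, seed = 1)
#' mean(ev$buckled)
#' @export
gen_events <- function(spec = population_spec(), n_events = 388,
                       model = c("length_only", "velocity_coupled"),
                       seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(spec, "population_spec"), n_events >= 1)
  tr <- spec$truth
  with_seed(seed, {
    ids <- integer(0)
    lens <- numeric(0)
    id <- 0L
    while (length(ids) < n_events) {
      id <- id + 1L
      n_i <- 1L + rgeom(1, prob = 1 / spec$repeats_dist$mean)
      L <- draw_lengths(spec$length_dist, 1)
      ids <- c(ids, rep(id, n_i))
      lens <- c(lens, rep(L, n_i))
    }
    ids <- ids[seq_len(n_events)]
    lens <- lens[seq_len(n_events)]
    v0 <- runif(n_events, spec$speed_dist$min, spec$speed_dist$max)
    if (model == "length_only") {
      p <- plogis((lens - tr$Lc_um) / tr$dLc_um)
    } else {
      B_printed <- tr$B * 1e21 # N m^2 -> nN um^2
      alpha <- tr$eta_nNs_um2 / (gamma_c() * B_printed)
      p <- plogis((lens - (alpha * v0)^(-1 / 3)) / tr$dLc_um)
    }
    out <- tibble(
      individual_id = sprintf("f%04d", ids),
      length_um = lens, speed_um_s = v0,
      buckled = rbinom(n_events, 1, p)
    ) |> assign_weights()
    attr(out, "truth") <- c(tr, list(model = model))
    out
  })
}

#' Generate a synthetic buckling contour track
#'
#' Forward model of a tracked buckling event: the Kirchhoff evolution at
#' activity `gamma` is sampled at the frame times `(t_i - 0)/t0` (scaled),
#' scaled to physical length `L_um`, rigidly rotated and translated, and
#' i.i.d. isotropic Gaussian noise of `noise_um` is added to every point.
#'
#' @param gamma supercritical activity coefficient.
#' @param t0_s shape time scale L^4 eta / B in seconds.
#' @param L_um contour length in um.
#' @param noise_um localization noise sd per coordinate, um.
#' @param n_frames number of frames.
#' @param frame_dt_s frame interval in seconds; `NULL` spreads the frames
#'   over 95% of the evolution (small amplitude to ~90 degrees).
#' @param rotation,translation rigid transform: radians and um (length 2).
#' @param species_B bending modulus carried with the track, N m^2.
#' @param n segment count of the underlying solver.
#' @param seed integer seed.
#' @return object of class `contour_track`: tibble `frames` (columns
#'   `frame`, `t_s`, `xy` list-column of matrices in um), plus `L_um`,
#'   `species_B`, validity mask, and the generating truth.
#' @export
gen_contour_track <- function(gamma, t0_s, L_um, noise_um = 0.3,
                              n_frames = 12, frame_dt_s = NULL,
                              rotation = 0, translation = c(0, 0),
                              species_B = 1.4e-16, n = 64, seed = NULL) {
  stopifnot(n_frames >= 3, t0_s > 0, L_um > 0)
  ev <- evolve(gamma, n = n)
  if (ev$decayed) abort("gamma is subcritical: no buckling track to generate")
  if (is.null(frame_dt_s)) {
    frame_dt_s <- 0.95 * ev$t_end * t0_s / (n_frames - 1)
  }
  t_s <- (seq_len(n_frames) - 1) * frame_dt_s
  tau <- t_s / t0_s
  if (any(tau > ev$t_end)) {
    warn("frame times exceed the 90-degree stopping time; track truncated")
    keep <- tau <= ev$t_end
    t_s <- t_s[keep]
    tau <- tau[keep]
  }
  ev2 <- evolve(gamma, n = n, times_scaled = tau)
  R <- matrix(
    c(cos(rotation), sin(rotation), -sin(rotation), cos(rotation)), 2, 2
  )
  with_seed(seed, {
    frames <- lapply(seq_along(tau), function(i) {
      # first snapshot of ev2 is t=0 which equals tau[1]=0
      k <- which.min(abs(ev2$snapshots$t_scaled - tau[i]))
      xy <- ev2$snapshots$xy[[k]] %*% t(R) * L_um
      xy <- sweep(xy, 2, translation, "+")
      if (noise_um > 0) xy <- xy + matrix(rnorm(length(xy), 0, noise_um),
                                          ncol = 2)
      xy
    })
    structure(
      list(
        frames = tibble(frame = seq_along(tau), t_s = t_s, xy = frames),
        L_um = L_um, species_B = species_B,
        valid = rep(TRUE, length(tau)),
        truth = list(
          gamma = gamma, t0_s = t0_s, rotation = rotation,
          translation = translation, noise_um = noise_um
        )
      ),
      class = "contour_track"
    )
  })
}

#' @export
print.contour_track <- function(x, ...) {
  cat("Contour track:", nrow(x$frames), "frames, L =", x$L_um, "um\n")
  invisible(x)
}

#' Generate a synthetic three-point bending curve
#'
#' Linear force-deflection data with slope 48 B / gap^3 (printed units
#' nN/um), multiplicative Gaussian noise on the force, and the pipette
#' deflection consistent with Hooke's law. A loading and an unloading branch
#' are produced.
#'
#' @param B bending modulus, N m^2.
#' @param pillar_gap_um distance between support pillars, um.
#' @param k_pipette_nN_um pipette spring constant, nN/um.
#' @param n_points samples per branch pair (split evenly).
#' @param noise_frac relative (multiplicative) force noise.
#' @param d_max_um maximum filament deflection, um.
#' @param seed integer seed.
#' @return tibble with `time_s`, `branch`, `filament_deflection_um`,
#'   `pipette_deflection_um`, `force_nN`; truth in `attr(, "truth")`.
#' @export
gen_bending_curve <- function(B, pillar_gap_um = 80, k_pipette_nN_um = 9.5,
                              n_points = 100, noise_frac = 0.05,
                              d_max_um = 5, seed = NULL) {
  stopifnot(B > 0, pillar_gap_um > 0, k_pipette_nN_um > 0, n_points >= 2)
  B_printed <- B * 1e21 # nN um^2
  slope <- 48 * B_printed / pillar_gap_um^3 # nN/um
  n_half <- ceiling(n_points / 2)
  d <- c(
    seq(0, d_max_um, length.out = n_half),
    seq(d_max_um, 0, length.out = n_points - n_half + 1)[-1]
  )
  branch <- rep(c("loading", "unloading"), c(n_half, n_points - n_half))
  with_seed(seed, {
    P <- slope * d
    if (noise_frac > 0) {
      P <- P * (1 + noise_frac * rnorm(length(P)))
    }
    out <- tibble(
      time_s = seq_along(d) - 1,
      branch = branch,
      filament_deflection_um = d,
      pipette_deflection_um = P / k_pipette_nN_um,
      force_nN = P
    )
    attr(out, "truth") <- list(
      B = B, slope_nN_um = slope, pillar_gap_um = pillar_gap_um,
      k_pipette_nN_um = k_pipette_nN_um, noise_frac = noise_frac
    )
    out
  })
}

#' Sample filament contour lengths
#'
#' Natural colony length distributions are very broad; the default family is
#' log-normal. A summary (mode and quartiles) is attached.
#'
#' @param dist_spec list with `family` ("lognormal" or "uniform") and its
#'   parameters.
#' @param n sample size (>= 0).
#' @param seed integer seed.
#' @return numeric vector of lengths (um) with attribute `summary`.
#' @export
gen_length_sample <- function(dist_spec = list(family = "lognormal",
                                               meanlog = log(150),
                                               sdlog = 0.6),
                              n = 1000, seed = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(numeric(0))
  with_seed(seed, {
    x <- draw_lengths(dist_spec, n)
    dens <- stats::density(x)
    attr(x, "summary") <- list(
      mode = dens$x[which.max(dens$y)],
      quartiles = quantile(x, c(0.25, 0.5, 0.75))
    )
    x
  })
}
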