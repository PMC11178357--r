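# Bead-chain Langevin simulator of filament-obstacle collisions.
#
# The filament is a chain of N beads of diameter sigma spaced sigma/2 apart,
# with harmonic bending stiffness kappa_b on the turning angle at each
# junction and a constant active force F_a per bead along the local tangent.
# The coarse-grained parameters map to the continuum ones via
# B ~ sigma kappa_b / 2 and f ~ 2 F_a / sigma; the per-length friction is
# eta = drag / (sigma / 2). Collisions with a V-shaped trap (WCA walls)
# reproduce the self-buckling threshold: scanning filament lengths and
# fitting the buckling outcomes with the logistic model recovers
# Gamma_c ~ 30.57.

#' Map continuum elastica parameters to bead-chain parameters
#'
#' kappa_b = 2 B / sigma and F_a = f sigma / 2 (simulation units).
#'
#' @param B bending modulus (simulation units, > 0).
#' @param f active force density (> 0).
#' @param sigma bead diameter (> 0).
#' @return list with `kappa_b` and `F_a`.
#' @examples
#' map_params(B = 1, f = 0.02, sigma = 1)
#' @export
map_params <- function(B, f, sigma) {
  if (B <= 0 || f <= 0 || sigma <= 0) abort("all arguments must be > 0")
  list(kappa_b = 2 * B / sigma, F_a = f * sigma / 2)
}

#' Construct a straight bead chain
#'
#' Beads are placed along -x from the head, spaced `sigma / 2`; the head
#' (bead 1) leads in the +x gliding direction.
#'
#' @param N number of beads (>= 8).
#' @param sigma bead diameter.
#' @param kappa_b bending stiffness (energy / rad^2).
#' @param F_a per-bead tangential active force.
#' @param drag per-bead drag coefficient.
#' @param kT thermal noise scale.
#' @param k_bond bond spring stiffness.
#' @param head at x-y position of the head bead.
#' @return an object of class `bead_chain`.
#' @export
bead_chain <- function(N = 32, sigma = 1, kappa_b = 2, F_a = 0.01,
                       drag = 1, kT = 5e-4, k_bond = 100,
                       head = c(0, 0)) {
  if (N < 8) abort("N must be >= 8")
  positions <- cbind(head[1] - (seq_len(N) - 1) * sigma / 2, head[2])
  structure(
    list(
      positions = positions, sigma = sigma, bond_length = sigma / 2,
      kappa_b = kappa_b, F_a = F_a, drag = drag, kT = kT, k_bond = k_bond
    ),
    class = "bead_chain"
  )
}

#' Construct a V-shaped trap
#'
#' Two straight WCA walls meeting at the apex, opening toward -x (the
#' incoming filament).
#'
#' @param apex apex position (x, y).
#' @param opening_angle opening angle in radians (0, pi).
#' @param wall_halflength length of each wall from the apex.
#' @param wca_epsilon,wca_sigma WCA interaction scales.
#' @return an object of class `v_trap`.
#' @export
v_trap <- function(apex = c(0, 0), opening_angle = pi / 2,
                   wall_halflength = 10, wca_epsilon = 1, wca_sigma = 0.5) {
  if (opening_angle <= 0 || opening_angle >= pi) {
    abort("opening angle must be in (0, pi)")
  }
  structure(
    list(
      apex = apex, opening_angle = opening_angle,
      wall_halflength = wall_halflength, wca_epsilon = wca_epsilon,
      wca_sigma = wca_sigma
    ),
    class = "v_trap"
  )
}

#' Run the overdamped Langevin dynamics
#'
#' Fixed-step Euler-Maruyama integration with bond, bending, active,
#' trap-wall and thermal forces. The default timestep is
#' `0.02 * drag * (sigma/2)^2 / kappa_b`, capped by the bond relaxation
#' time. Deterministic given the R RNG state (use `set.seed()` or `seed`).
#'
#' @param chain a [bead_chain()].
#' @param trap a [v_trap()] or `NULL` for free gliding.
#' @param t_end simulated time.
#' @param dt timestep; `NULL` for the stability default.
#' @param stride record every `stride`-th step.
#' @param seed optional integer seed.
#' @param dev_stop_frac online-stop threshold: end the run once the
#'   transverse deviation exceeds this fraction of the contour length for
#'   `sustain_time` (0 disables).
#' @param sustain_time time the deviation must stay above threshold.
#' @param noise_interval time between thermal kicks: the noise is applied
#'   as accumulated Brownian increments on this (sub-physical) interval.
#' @return object of class `bead_trajectory`: tibble `snapshots`
#'   (`t`, `bead`, `x`, `y`), per-frame `deviation` and `energy` series,
#'   `collision_time`, `buckled`, `buckle_time`.
#' @export
run_bead_chain <- function(chain, trap = NULL, t_end = 1000, dt = NULL,
                           stride = NULL, seed = NULL,
                           dev_stop_frac = 0, sustain_time = 0,
                           noise_interval = 0.02) {
  stopifnot(inherits(chain, "bead_chain"))
  if (is.null(dt)) {
    dt_bend <- 0.02 * chain$drag * chain$bond_length^2 / chain$kappa_b
    dt_bond <- 0.2 * chain$drag / chain$k_bond
    dt <- min(dt_bend, dt_bond)
  }
  if (is.null(stride)) stride <- max(1L, floor(t_end / dt / 400))
  trap_vec <- if (is.null(trap)) numeric(0) else
    c(trap$apex, trap$opening_angle, trap$wall_halflength)
  wca_sigma <- if (is.null(trap)) 0.5 else trap$wca_sigma
  wca_eps <- if (is.null(trap)) 1 else trap$wca_epsilon
  noise_stride <- max(1L, as.integer(round(noise_interval / dt)))
  runner <- function() {
    bead_chain_run_cpp(
      chain$positions, chain$k_bond, chain$bond_length, chain$kappa_b,
      chain$F_a, chain$drag, chain$kT, dt, t_end, as.integer(stride),
      trap_vec, wca_sigma, wca_eps, dev_stop_frac, sustain_time,
      noise_stride
    )
  }
  res <- if (is.null(seed)) runner() else with_seed(seed, runner())
  if (res$error_step >= 0) {
    abort(sprintf(
      "bond stretch exceeded 20%% at step %d: unstable timestep?",
      as.integer(res$error_step)
    ))
  }
  N <- nrow(chain$positions)
  snapshots <- tibble(
    t = rep(res$t, each = N),
    bead = rep(seq_len(N), times = length(res$t)),
    x = as.vector(t(res$x)),
    y = as.vector(t(res$y))
  )
  structure(
    list(
      snapshots = snapshots,
      series = tibble(
        t = res$t, deviation = res$deviation, energy = res$energy,
        head_contact = res$head_contact
      ),
      chain = chain, trap = trap, dt = dt, stride = stride,
      collision_time = res$collision_time,
      buckled = res$buckled, buckle_time = res$buckle_time,
      L = (N - 1) * chain$bond_length
    ),
    class = "bead_trajectory"
  )
}

#' @export
print.bead_trajectory <- function(x, ...) {
  cat("Bead-chain trajectory:", length(unique(x$snapshots$t)), "frames,",
    nrow(x$chain$positions), "beads, dt =", format(x$dt, digits = 3), "\n")
  if (is.finite(x$collision_time)) {
    cat("  collision at t =", format(x$collision_time, digits = 4),
        if (x$buckled) " -> buckled" else " -> no buckling", "\n")
  }
  invisible(x)
}

#' Classify a collision trajectory as buckling or not
#'
#' Buckling means the maximum transverse deviation of the chain from its
#' head-tail chord exceeds `threshold_frac * L` for a sustained window
#' after the collision.
#'
#' @param trajectory a `bead_trajectory` containing a collision.
#' @param threshold_frac deviation threshold as a fraction of contour
#'   length.
#' @param sustain_frames number of consecutive recorded frames above
#'   threshold required.
#' @return logical: `TRUE` for buckling.
#' @export
classify_buckling <- function(trajectory, threshold_frac = 0.15,
                              sustain_frames = 10) {
  stopifnot(inherits(trajectory, "bead_trajectory"))
  if (!is.finite(trajectory$collision_time)) {
    abort("trajectory contains no collision with the trap")
  }
  # runs ended early by the online criterion are buckling by definition
  if (isTRUE(trajectory$buckled)) return(TRUE)
  post <- trajectory$series[
    trajectory$series$t >= trajectory$collision_time,
  ]
  above <- post$deviation > threshold_frac * trajectory$L
  if (!any(above)) return(FALSE)
  r <- rle(above)
  any(r$values & r$lengths >= sustain_frames)
}

#' Estimate the buckling threshold from collision simulations
#'
#' Runs seeded collision simulations over a scan of filament lengths
#' bracketing the theoretical critical length Lc = (k B / f)^(1/3), fits
#' the logistic outcome model with [fit_logistic_length()], and converts
#' the fitted median length to the dimensionless threshold
#' Gamma_c = Lc^3 f / B.
#'
#' @param B,f continuum parameters in simulation units.
#' @param sigma bead diameter.
#' @param lengths filament lengths to scan; default 12 values spanning
#'   0.6-1.8 of the theoretical Lc.
#' @param reps replicates per length (>= 4).
#' @param seed integer seed for the whole scan.
#' @param kT thermal noise scale.
#' @param drag per-bead drag.
#' @param threshold_frac,sustain_time classification parameters.
#' @param efolds observation horizon per run, in units of the linear
#'   growth time t0(L) / rate(Gamma) (floored at `rate_floor` near the
#'   threshold where the rate vanishes).
#' @param rate_floor floor on the scaled growth rate used for the horizon.
#' @param progress print one line per length.
#' @return object of class `threshold_scan`: `gamma_c_estimate`, `Lc_hat`,
#'   the logistic fit, and the outcome table.
#' @export
threshold_scan <- function(B = 1, f = 30.5722 / 12^3, sigma = 1,
                           lengths = NULL, reps = 8, seed = 1,
                           kT = 1e-3, drag = 1, threshold_frac = 0.15,
                           sustain_time = 50, efolds = 8, rate_floor = 40,
                           progress = FALSE) {
  stopifnot(reps >= 4)
  if (f <= 0) {
    # no active force: no buckling is possible at any length
    abort("bracketing error: zero active force never buckles")
  }
  Lc_th <- (gamma_c() * B / f)^(1 / 3)
  if (is.null(lengths)) lengths <- seq(0.6, 1.8, length.out = 12) * Lc_th
  if (min(lengths) > Lc_th || max(lengths) < Lc_th) {
    abort("lengths must bracket the theoretical critical length")
  }
  mp <- map_params(B, f, sigma)
  eta <- drag / (sigma / 2)
  trap <- v_trap(
    apex = c(0, 0), opening_angle = pi / 2,
    wall_halflength = 1.4 * max(lengths), wca_epsilon = 1,
    wca_sigma = sigma / 2
  )
  rc <- 2^(1 / 6) * sigma / 2

  runs <- with_seed(seed, {
    rows <- list()
    for (li in seq_along(lengths)) {
      L <- lengths[li]
      # each bead carries sigma/2 of contour (consistent with f = 2 F_a /
      # sigma), so the represented length is N * sigma / 2
      N <- max(8L, as.integer(round(2 * L / sigma)))
      L_chain <- N * sigma / 2
      gamma_L <- L_chain^3 * f / B
      t0 <- eta * L_chain^4 / B
      rate <- leading_mode(max(gamma_L, 1), 32)$rate
      t_obs <- efolds * t0 / max(rate, rate_floor)
      v0 <- mp$F_a / drag
      t_approach <- 2 * sigma / v0
      for (r in seq_len(reps)) {
        chain <- bead_chain(
          N = N, sigma = sigma, kappa_b = mp$kappa_b, F_a = mp$F_a,
          drag = drag, kT = kT, head = c(-(rc + 2 * sigma), 0)
        )
        traj <- run_bead_chain(chain, trap,
          t_end = t_approach + t_obs,
          dev_stop_frac = threshold_frac * 1.2, sustain_time = sustain_time
        )
        out <- if (is.finite(traj$collision_time)) {
          classify_buckling(traj, threshold_frac,
            sustain_frames = max(3, ceiling(sustain_time /
              (traj$dt * traj$stride)))
          )
        } else {
          NA
        }
        rows[[length(rows) + 1]] <- tibble(
          length = L_chain, N = N, rep = r, gamma = gamma_L,
          buckled = as.integer(out)
        )
      }
      if (progress) {
        done <- list_rbind(rows)
        frac <- mean(done$buckled[done$length == L_chain], na.rm = TRUE)
        message(sprintf("L = %.2f (N = %d): buckling fraction %.2f",
                        L_chain, N, frac))
      }
    }
    list_rbind(rows)
  })
  runs <- filter(runs, !is.na(.data$buckled))
  if (length(unique(runs$buckled)) < 2) {
    abort("bracketing error: all outcomes identical across the scan")
  }
  events <- tibble(
    individual_id = sprintf("L%02d_r%02d",
      match(runs$length, sort(unique(runs$length))), runs$rep),
    length_um = runs$length, buckled = runs$buckled
  )
  fit <- fit_logistic_length(events)
  Lc_hat <- unname(fit$estimate["Lc_um"])
  structure(
    list(
      gamma_c_estimate = Lc_hat^3 * f / B,
      Lc_hat = Lc_hat, Lc_theory = Lc_th, fit = fit, outcomes = runs,
      B = B, f = f, sigma = sigma, kT = kT, reps = reps, seed = seed
    ),
    class = "threshold_scan"
  )
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("Bead-chain buckling threshold scan\n")
  cat(sprintf(
    "  Lc_hat = %.3f (theory %.3f)   Gamma_c estimate = %.3f\n",
    x$Lc_hat, x$Lc_theory, x$gamma_c_estimate
  ))
  cat("  outcomes:", nrow(x$outcomes), "runs over",
    length(unique(x$outcomes$length)), "lengths\n")
  invisible(x)
}

#' @export
autoplot.bead_trajectory <- function(object, every = 10, ...) {
  tt <- unique(object$snapshots$t)
  keep <- tt[unique(c(seq(1, length(tt), by = every), length(tt)))]
  df <- filter(object$snapshots, .data$t %in% keep)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
    group = .data$t, colour = .data$t
  )) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (sigma)", y = "y (sigma)", colour = "t")
  if (!is.null(object$trap)) {
    tr <- object$trap
    th <- c(pi - tr$opening_angle / 2, pi + tr$opening_angle / 2)
    walls <- tibble(
      x = tr$apex[1], y = tr$apex[2],
      xend = tr$apex[1] + tr$wall_halflength * cos(th),
      yend = tr$apex[2] + tr$wall_halflength * sin(th)
    )
    p <- p + ggplot2::geom_segment(
      data = walls,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      inherit.aes = FALSE, linewidth = 1
    )
  }
  p
}
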