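# Nonlinear shape dynamics of the buckling filament.
#
# The planar Kirchhoff balance for a filament pushed by a tangential force
# density against a head-pinning obstacle, with isotropic substrate friction,
# reads in scaled units (s in [0,1], t in units of t0 = L^4 eta / B)
#
#   d2phi/ds2 - Gamma * Int_s^1 sin(phi(s') - phi(s)) ds'
#             - Int_s^1 (1-s') cos(phi(s') - phi(s)) dphi/dt(s') ds'
#             - (1-s) * Int_0^s cos(phi(s') - phi(s)) dphi/dt(s') ds' = 0.
#
# Discretized on n segment midpoints (method of lines) this is a mass-matrix
# ODE system M(phi) dphi/dt = b(phi): the friction integrals couple all
# rates, so every step solves a dense n x n system. Torque-free ends
# (kappa = dphi/ds = 0 at s = 0 and s = 1) are imposed by ghost-node
# reflection in the second-difference operator. The head is pinned by
# construction: positions are reconstructed by integrating the tangent from
# s = 0.

segment_midpoints <- function(n) (seq_len(n) - 0.5) / n

# second difference with zero-curvature (Neumann) ends
d2_apply <- function(phi, h) {
  n <- length(phi)
  ghosted <- c(phi[1], phi, phi[n])
  (ghosted[1:n] - 2 * phi + ghosted[3:(n + 2)]) / h^2
}

# friction mass matrix M_ij = h * (1 - max(s_i, s_j)) * cos(phi_j - phi_i)
friction_matrix <- function(phi, s) {
  h <- 1 / length(s)
  w <- 1 - outer(s, s, pmax)
  h * w * cos(outer(phi, phi, function(a, b) b - a))
}

# active-bending drive b_i = d2phi_i - Gamma * h * sum_{j>i} sin(phi_j - phi_i)
drive_vector <- function(phi, gamma, h) {
  n <- length(phi)
  smat <- sin(outer(phi, phi, function(a, b) b - a))
  smat[lower.tri(smat, diag = TRUE)] <- 0
  d2_apply(phi, h) - gamma * h * rowSums(smat)
}

kirchhoff_rhs <- function(t, phi, parms) {
  s <- parms$s
  h <- 1 / length(s)
  M <- friction_matrix(phi, s)
  b <- drive_vector(phi, parms$gamma, h)
  list(solve(M, b))
}

# Linearization about the straight state phi = 0:
#   M0 dphi/dt = A phi,  A = D2 - Gamma * W,  W_ij = h (j > i),
#   W_ii = -h * (n - i). Used for the initial condition and for the
#   leading growth rate.
linear_operator <- function(gamma, n) {
  h <- 1 / n
  s <- segment_midpoints(n)
  D2 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    D2[i, i] <- -2 / h^2
    if (i > 1) D2[i, i - 1] <- 1 / h^2
    if (i < n) D2[i, i + 1] <- 1 / h^2
  }
  D2[1, 1] <- D2[1, 1] + 1 / h^2
  D2[n, n] <- D2[n, n] + 1 / h^2
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- h
  diag(W) <- -h * (n - seq_len(n))
  M0 <- friction_matrix(numeric(n), s)
  list(A = D2 - gamma * W, M0 = M0, s = s)
}

# leading eigenpair of M0^-1 A, excluding the neutral rigid-rotation mode
leading_mode <- function(gamma, n) {
  op <- linear_operator(gamma, n)
  ev <- eigen(solve(op$M0, op$A))
  vals <- Re(ev$values)
  vecs <- Re(ev$vectors)
  # the constant vector is neutral (eigenvalue ~0); drop near-constant modes
  keep <- apply(vecs, 2, function(v) sd(v) / max(abs(v)) > 1e-6)
  idx <- which(keep)[which.max(vals[keep])]
  v <- vecs[, idx]
  v <- v - mean(v)
  # eigen() returns an arbitrary sign; fix the head angle positive so all
  # evolutions (hence all library members) buckle the same way
  list(rate = vals[idx], mode = v / v[1])
}

#' Reconstruct the x-y polyline of a tangent-angle field
#'
#' Cumulative midpoint quadrature of (cos phi, sin phi) from the head:
#' returns n + 1 points with the head at the origin, consecutive spacing
#' exactly 1/n and total arclength exactly 1 (scaled units).
#'
#' @param phi orientation angles at the n segment midpoints, radians.
#' @return an (n + 1) x 2 matrix of coordinates.
#' @examples
#' to_xy(rep(0, 8)) # straight unit segment along +x
#' @export
to_xy <- function(phi) {
  stopifnot(is.numeric(phi), all(is.finite(phi)))
  h <- 1 / length(phi)
  cbind(
    c(0, cumsum(h * cos(phi))),
    c(0, cumsum(h * sin(phi)))
  )
}

#' Evolve the nonlinear buckling dynamics at fixed activity
#'
#' Integrates the discretized shape equation from a small-amplitude copy of
#' the leading linear mode until the head angle reaches `stop_head_angle`
#' (default 90 degrees), storing 64 snapshots by default. For subcritical
#' `gamma` the perturbation decays and a decay flag is returned instead of a
#' snapshot series.
#'
#' @param gamma activity coefficient Gamma = L^3 f / B (> 0).
#' @param n number of segments (>= 16).
#' @param init_amplitude initial head angle of the seeded linear mode, rad.
#' @param stop_head_angle head angle terminating the run, rad.
#' @param n_snapshots number of stored snapshots.
#' @param times_scaled optional explicit snapshot times (overrides the
#'   geometric default grid).
#' @param rtol,atol integrator tolerances (deSolve `lsodar`).
#' @return an object of class `kirchhoff_evolution`: tibble `snapshots`
#'   (columns `t_scaled`, `head_angle`, `phi`, `xy`), the growth `rate` of
#'   the seeded mode, and `decayed`.
#' @export
evolve <- function(gamma, n = 64, init_amplitude = 0.01,
                   stop_head_angle = pi / 2, n_snapshots = 64,
                   times_scaled = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(gamma > 0, n >= 16, init_amplitude > 0, init_amplitude < 0.5)
  lead <- leading_mode(gamma, n)
  phi0 <- init_amplitude * lead$mode
  parms <- list(gamma = gamma, s = segment_midpoints(n))

  if (lead$rate <= 0) {
    # subcritical: confirm decay over a few relaxation times
    t_probe <- 5 / max(abs(lead$rate), 1)
    out <- deSolve::ode(phi0, c(0, t_probe), kirchhoff_rhs, parms,
      method = "lsoda", rtol = rtol, atol = atol
    )
    final <- out[nrow(out), -1]
    return(structure(
      list(
        gamma = gamma, n = n, decayed = max(abs(final)) < max(abs(phi0)),
        rate = lead$rate, snapshots = NULL
      ),
      class = "kirchhoff_evolution"
    ))
  }

  rootfun <- function(t, phi, parms) abs(phi[1]) - stop_head_angle
  t_end <- NA_real_
  phi_now <- phi0
  t_now <- 0
  # initial horizon from the linear rate; grown geometrically because the
  # eigenvalue only bounds the early growth (the late, nonlinear approach
  # to 90 degrees can be much slower, especially at large Gamma)
  chunk <- 4 / lead$rate
  for (k in 1:60) {
    tt <- seq(t_now, t_now + chunk, length.out = 33)
    out <- deSolve::lsodar(phi_now, tt, kirchhoff_rhs, parms,
      rtol = rtol, atol = atol, rootfunc = rootfun
    )
    t_last <- out[nrow(out), 1]
    phi_now <- out[nrow(out), -1]
    if (t_last < tt[length(tt)] - 1e-12 ||
      abs(rootfun(t_last, phi_now, parms)) < 1e-8) {
      t_end <- t_last
      break
    }
    if (max(abs(phi_now)) < init_amplitude / 10) {
      return(structure(
        list(
          gamma = gamma, n = n, decayed = TRUE, rate = lead$rate,
          snapshots = NULL
        ),
        class = "kirchhoff_evolution"
      ))
    }
    t_now <- t_last
    chunk <- chunk * 1.5
  }
  if (is.na(t_end)) {
    abort(sprintf(
      "integrator did not reach the stopping head angle (gamma=%g, last t=%g)",
      gamma, t_now
    ))
  }

  if (is.null(times_scaled)) {
    # geometric spacing emphasising the nonlinear stage; first snapshot at 0
    q <- (1 / 100)^(1 / (n_snapshots - 2))
    times_scaled <- c(0, t_end * q^((n_snapshots - 2):0))
  } else {
    if (any(times_scaled > t_end + 1e-12)) {
      warn("requested snapshot times exceed the stopping time; truncated")
      times_scaled <- times_scaled[times_scaled <= t_end + 1e-12]
    }
    if (times_scaled[1] > 0) times_scaled <- c(0, times_scaled)
    if (length(times_scaled) < 2) {
      abort("fewer than 2 snapshot times remain inside the evolution window")
    }
  }
  out <- deSolve::ode(phi0, times_scaled, kirchhoff_rhs, parms,
    method = "lsoda", rtol = rtol, atol = atol
  )
  phis <- lapply(seq_len(nrow(out)), function(i) unname(out[i, -1]))
  snapshots <- tibble(
    t_scaled = out[, 1],
    head_angle = map_dbl(phis, 1),
    phi = phis,
    xy = map(phis, to_xy)
  )
  structure(
    list(
      gamma = gamma, n = n, decayed = FALSE, rate = lead$rate,
      t_end = t_end, snapshots = snapshots
    ),
    class = "kirchhoff_evolution"
  )
}

#' @export
print.kirchhoff_evolution <- function(x, ...) {
  cat("Kirchhoff evolution: gamma =", format(x$gamma, digits = 6),
      "n =", x$n, "\n")
  if (x$decayed) {
    cat("  subcritical: perturbation decayed (rate ",
      format(x$rate, digits = 4), ")\n",
      sep = ""
    )
  } else {
    cat(
      "  ", nrow(x$snapshots), "snapshots to t =",
      format(max(x$snapshots$t_scaled), digits = 4),
      "(head angle", format(180 / pi * tail(x$snapshots$head_angle, 1),
        digits = 3
      ), "deg)\n"
    )
  }
  invisible(x)
}

#' Post-buckling rotation rate
#'
#' Above threshold the buckled filament settles into a rotor state
#' phi(s, t) = phi(s) + omega t about the pinned head. The rate is measured
#' from the late-time linear drift of the head angle in an extended
#' integration (stopping criterion disabled).
#'
#' @param gamma supercritical activity coefficient.
#' @param n segment count.
#' @param init_amplitude seed amplitude; its sign selects the rotation sense.
#' @param horizon_factor integration horizon as a multiple of the time to
#'   reach a 90-degree head angle.
#' @return list with `omega` (scaled rad per unit t), `converged` (late-time
#'   drift is linear), and the sampled head angle series.
#' @export
measure_rotor_omega <- function(gamma, n = 48, init_amplitude = 0.01,
                                horizon_factor = 8) {
  lead <- leading_mode(gamma, n)
  if (lead$rate <= 0) {
    return(list(omega = NA_real_, converged = FALSE, series = NULL))
  }
  base <- evolve(gamma, n,
    init_amplitude = abs(init_amplitude),
    stop_head_angle = pi / 2
  )
  t90 <- base$t_end
  parms <- list(gamma = gamma, s = segment_midpoints(n))
  phi0 <- abs(init_amplitude) * lead$mode * sign(init_amplitude)
  tt <- seq(0, horizon_factor * t90, length.out = 241)
  out <- deSolve::ode(phi0, tt, kirchhoff_rhs, parms,
    method = "lsoda", rtol = 1e-8, atol = 1e-10
  )
  series <- tibble(t_scaled = out[, 1], head_angle = out[, 2])
  late <- filter(series, .data$t_scaled >= 0.75 * max(.data$t_scaled))
  fit <- lm(head_angle ~ t_scaled, data = late)
  omega <- unname(coef(fit)[2])
  lin_res <- sd(fit$residuals) / (abs(omega) * diff(range(late$t_scaled)))
  list(omega = omega, converged = is.finite(lin_res) && lin_res < 0.05,
       series = series)
}

#' Build the interpolation-ready library of buckling profiles
#'
#' Evolves the shape dynamics for a log-spaced grid of activity coefficients
#' covering length ratios L/Lc from `lc_ratio_min` to `lc_ratio_max`
#' (Gamma = gamma_c * ratio^3), storing `n_snapshots` snapshots per member
#' from small amplitude to a ~90-degree head angle. The library supports
#' continuous interpolation in (Gamma, t) via [library_contour()].
#'
#' @param lc_ratio_min,lc_ratio_max range of L/Lc covered (1 < min < max).
#' @param count number of Gamma values.
#' @param n segment count per member.
#' @param n_snapshots snapshots per member.
#' @param init_amplitude seed amplitude for each evolution.
#' @return an object of class `profile_library`.
#' @export
build_profile_library <- function(lc_ratio_min = 1.05, lc_ratio_max = 9,
                                  count = 30, n = 64, n_snapshots = 64,
                                  init_amplitude = 0.01) {
  stopifnot(1 < lc_ratio_min, lc_ratio_min < lc_ratio_max,
            lc_ratio_max <= 9 * 1.05^(1 / 3))
  gc <- linear_threshold_numeric("pinned_free_tangential")$gamma_c
  gamma_grid <- gc * exp(seq(log(lc_ratio_min^3), log(lc_ratio_max^3),
    length.out = count
  ))
  members <- lapply(gamma_grid, function(g) {
    ev <- tryCatch(
      evolve(g, n = n, init_amplitude = init_amplitude,
             n_snapshots = n_snapshots),
      error = function(e) {
        abort(sprintf("library build failed at gamma=%g: %s", g,
                      conditionMessage(e)))
      }
    )
    if (ev$decayed) abort(sprintf("library member at gamma=%g decayed", g))
    list(
      gamma = g,
      times = ev$snapshots$t_scaled,
      phi = do.call(rbind, ev$snapshots$phi)
    )
  })
  structure(
    list(
      gamma_grid = gamma_grid, members = members, n = n,
      n_snapshots = n_snapshots, init_amplitude = init_amplitude,
      gamma_c = gc
    ),
    class = "profile_library"
  )
}

#' @export
print.profile_library <- function(x, ...) {
  cat("Profile library:", length(x$gamma_grid), "Gamma values in [",
    format(min(x$gamma_grid), digits = 5), ",",
    format(max(x$gamma_grid), digits = 5), "],",
    x$n_snapshots, "snapshots each, n =", x$n, "\n")
  invisible(x)
}

# linear interpolation of a member's angle field at scaled time t
member_phi_at <- function(member, t) {
  times <- member$times
  if (t < times[1] - 1e-12 || t > times[length(times)] + 1e-12) return(NULL)
  t <- min(max(t, times[1]), times[length(times)])
  k <- findInterval(t, times, all.inside = TRUE)
  u <- (t - times[k]) / (times[k + 1] - times[k])
  (1 - u) * member$phi[k, ] + u * member$phi[k + 1, ]
}

#' Time range covered by the library at an activity value
#'
#' The stopping time (head angle ~90 degrees) of each member shrinks
#' rapidly with Gamma; between members it is interpolated log-linearly in
#' Gamma.
#'
#' @param library a [build_profile_library()] object.
#' @param gamma activity coefficient inside the grid.
#' @return length-2 numeric: valid scaled-time interval for interpolation.
#' @export
library_time_range <- function(library, gamma) {
  gg <- library$gamma_grid
  if (gamma < gg[1] || gamma > gg[length(gg)]) {
    abort("gamma outside the library grid")
  }
  k <- findInterval(gamma, gg, all.inside = TRUE)
  u <- (log(gamma) - log(gg[k])) / (log(gg[k + 1]) - log(gg[k]))
  T1 <- max(library$members[[k]]$times)
  T2 <- max(library$members[[k + 1]]$times)
  c(0, exp((1 - u) * log(T1) + u * log(T2)))
}

#' Interpolated buckling contour from the profile library
#'
#' Linear interpolation of the tangent-angle field in scaled time within
#' each neighbouring library member, then in log Gamma across members. The
#' two members are phase-aligned before blending: a query time is mapped to
#' the same fraction of each member's stopping time, which itself
#' interpolates log-linearly in Gamma. The contour is reconstructed from
#' the blended angle field, so inextensibility is preserved exactly.
#'
#' @param library a `profile_library`.
#' @param gamma activity coefficient inside the grid.
#' @param t_scaled scaled time inside [library_time_range()].
#' @return (n + 1) x 2 contour matrix (scaled units, head at origin), or
#'   `NULL` when `(gamma, t_scaled)` falls outside the grid hull.
#' @export
library_contour <- function(library, gamma, t_scaled) {
  phi <- library_phi(library, gamma, t_scaled)
  if (is.null(phi)) return(NULL)
  to_xy(phi)
}

# angle-field version of library_contour (used by the fitters)
library_phi <- function(library, gamma, t_scaled) {
  gg <- library$gamma_grid
  if (gamma < gg[1] - 1e-12 || gamma > gg[length(gg)] + 1e-12) return(NULL)
  gamma <- min(max(gamma, gg[1]), gg[length(gg)])
  k <- findInterval(gamma, gg, all.inside = TRUE)
  u <- (log(gamma) - log(gg[k])) / (log(gg[k + 1]) - log(gg[k]))
  m1 <- library$members[[k]]
  m2 <- library$members[[k + 1]]
  T1 <- max(m1$times)
  T2 <- max(m2$times)
  Tg <- exp((1 - u) * log(T1) + u * log(T2))
  if (t_scaled < -1e-12 || t_scaled > Tg * (1 + 1e-9)) return(NULL)
  phase <- min(max(t_scaled / Tg, 0), 1)
  p1 <- member_phi_at(m1, phase * T1)
  p2 <- member_phi_at(m2, phase * T2)
  if (is.null(p1) || is.null(p2)) return(NULL)
  (1 - u) * p1 + u * p2
}

#' @describeIn evolve plot stored contours coloured by time.
#' @param object,x a `kirchhoff_evolution`.
#' @param every plot every `every`-th snapshot.
#' @param ... unused.
#' @export
autoplot.kirchhoff_evolution <- function(object, every = 8, ...) {
  if (object$decayed) abort("nothing to plot: evolution decayed")
  idx <- unique(c(seq(1, nrow(object$snapshots), by = every),
                  nrow(object$snapshots)))
  df <- list_rbind(lapply(idx, function(i) {
    xy <- object$snapshots$xy[[i]]
    tibble(
      t_scaled = object$snapshots$t_scaled[i],
      x = xy[, 1], y = xy[, 2]
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
    group = .data$t_scaled, colour = .data$t_scaled
  )) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x / L", y = "y / L", colour = "t / t0",
      title = sprintf("Buckling shape evolution, Gamma = %.3g", object$gamma)
    )
}
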