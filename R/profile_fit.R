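# Fitting library profiles to observed buckling contour tracks.
#
# Each observed frame is an x-y polyline of the filament midline (um). The
# theoretical shape at activity Gamma and scaled time tau comes from the
# profile library; fitting minimizes the mean squared Euclidean distance
# between arclength-corresponding points of the two curves (both resampled
# to a common number of points), with the rigid rotation and translation
# solved in closed form (2-D orthogonal Procrustes) at every objective
# evaluation. A per-frame fit seeds a global fit in which one (Gamma, t0,
# time offset) set and one rigid transform must explain all frames
# simultaneously; Gamma and t0 convert to the active force density
# f = Gamma B / L^3 and the friction coefficient eta = t0 B / L^4 with the
# species-median bending modulus B.

#' Resample a polyline to equal arclength spacing
#'
#' @param polyline m x 2 numeric matrix (m >= 2), finite coordinates.
#' @param n number of output points (endpoints preserved).
#' @return n x 2 matrix equally spaced in arclength.
#' @export
resample_contour <- function(polyline, n = 64) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2 || !all(is.finite(polyline))) {
    abort("polyline needs >= 2 finite points")
  }
  seg <- sqrt(rowSums(diff(polyline)^2))
  if (sum(seg) <= 0) abort("degenerate (zero-length) polyline")
  arc <- c(0, cumsum(seg))
  target <- seq(0, arc[length(arc)], length.out = n)
  cbind(
    approx(arc, polyline[, 1], target, ties = "ordered")$y,
    approx(arc, polyline[, 2], target, ties = "ordered")$y
  )
}

polyline_length <- function(polyline) {
  sum(sqrt(rowSums(diff(as.matrix(polyline))^2)))
}

# Optimal rotation+translation mapping model points onto data points
# (least squares over corresponding rows, rotation only - no reflection).
# Returns the transform and the mean squared residual distance.
procrustes_rigid <- function(model, data) {
  mc <- colMeans(model)
  dc <- colMeans(data)
  A <- sweep(data, 2, dc)
  Bm <- sweep(model, 2, mc)
  # 2-D: optimal angle from the cross-covariance
  num <- sum(Bm[, 1] * A[, 2] - Bm[, 2] * A[, 1])
  den <- sum(Bm[, 1] * A[, 1] + Bm[, 2] * A[, 2])
  theta <- atan2(num, den)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  fitted <- sweep(Bm %*% t(R), 2, dc, "+")
  list(
    rotation = theta,
    translation = dc - as.vector(R %*% mc),
    residual = mean(rowSums((fitted - data)^2)),
    fitted = fitted
  )
}

# residual of a library shape (gamma, tau) against one resampled frame (um)
frame_residual <- function(library, gamma, tau, data_um, L_um, n_points) {
  phi <- library_phi(library, gamma, tau)
  if (is.null(phi)) return(list(residual = Inf))
  model <- resample_contour(to_xy(phi) * L_um, n_points)
  procrustes_rigid(model, data_um)
}

#' Fit a single frame against the profile library
#'
#' Scans all library grid nodes for the best (Gamma, tau) seed, then
#' refines by Nelder-Mead in (log Gamma, log tau) with the rigid transform
#' solved in closed form at each evaluation. Both mirror images of the
#' theoretical shape are tried (the buckling direction is not fixed).
#'
#' @param polyline_um observed frame, matrix of x-y points in um.
#' @param library a [build_profile_library()] object.
#' @param L_um filament contour length in um.
#' @param n_points resampling resolution of the residual metric.
#' @param coarse_times number of time nodes scanned per library member.
#' @return one-row tibble: `gamma`, `t_scaled`, `mirrored`, `rotation`,
#'   `tx_um`, `ty_um`, `residual_um2`, `converged`, `uninformative` (straight
#'   contour best matched at the small-amplitude end of the grid).
#' @export
fit_frame <- function(polyline_um, library, L_um, n_points = 64,
                      coarse_times = 16) {
  data <- resample_contour(polyline_um, n_points)
  best <- list(residual = Inf)
  for (mirrored in c(FALSE, TRUE)) {
    dd <- if (mirrored) cbind(data[, 1], -data[, 2]) else data
    for (k in seq_along(library$gamma_grid)) {
      member <- library$members[[k]]
      tt <- member$times
      idx <- unique(round(seq(1, length(tt), length.out = coarse_times)))
      for (i in idx) {
        r <- frame_residual(
          library, library$gamma_grid[k], tt[i], dd, L_um, n_points
        )
        if (r$residual < best$residual) {
          best <- c(r, list(
            gamma = library$gamma_grid[k], tau = tt[i],
            mirrored = mirrored
          ))
        }
      }
    }
  }
  dd <- if (best$mirrored) cbind(data[, 1], -data[, 2]) else data
  obj <- function(p) {
    g <- exp(p[1])
    tau <- exp(p[2])
    r <- frame_residual(library, g, tau, dd, L_um, n_points)
    r$residual
  }
  start <- c(log(best$gamma), log(max(best$tau, 1e-12)))
  opt <- optim(start, obj,
    method = "Nelder-Mead",
    control = list(maxit = 800, reltol = 1e-14)
  )
  g <- exp(opt$par[1])
  tau <- exp(opt$par[2])
  r <- frame_residual(library, g, tau, dd, L_um, n_points)
  if (!is.finite(r$residual)) { # refinement left the hull; keep the seed
    g <- best$gamma
    tau <- best$tau
    r <- frame_residual(library, g, tau, dd, L_um, n_points)
  }
  tmin <- min(library$members[[
    findInterval(g, library$gamma_grid, all.inside = TRUE)
  ]]$times[2])
  tibble(
    gamma = g, t_scaled = tau, mirrored = best$mirrored,
    rotation = r$rotation, tx_um = r$translation[1],
    ty_um = r$translation[2], residual_um2 = r$residual,
    converged = opt$convergence == 0,
    uninformative = tau <= tmin
  )
}

# residual over all (valid) frames for global parameters; single shared
# rigid transform fitted in closed form over the concatenated points.
# Parameters outside the library hull are soft-clamped with a quadratic
# penalty so the simplex can recover from infeasible iterates.
global_residual <- function(library, gamma, t0, t_offset, frames_um, t_s,
                            L_um, mirrored, n_points) {
  gg <- library$gamma_grid
  g_clamped <- min(max(gamma, gg[1]), gg[length(gg)])
  pen <- (log(gamma) - log(g_clamped))^2
  tr <- library_time_range(library, g_clamped)
  tau <- (t_s - t_offset) / t0
  excess <- pmax(tau - tr[2], 0) / tr[2] + pmax(-tau, 0) / max(tr[2], 1e-12)
  pen <- pen + sum(excess^2)
  tau <- pmin(pmax(tau, 0), tr[2])
  models <- lapply(tau, function(tt) {
    resample_contour(to_xy(library_phi(library, g_clamped, tt)) * L_um,
                     n_points)
  })
  model <- do.call(rbind, models)
  data <- do.call(rbind, frames_um)
  if (mirrored) data <- cbind(data[, 1], -data[, 2])
  procrustes_rigid(model, data)$residual + pen * L_um^2
}

#' Global fit of a contour track
#'
#' Joint minimization of the summed squared contour distance of all valid
#' frames over (Gamma, t0, time offset) with a single shared rigid
#' transform, seeded by averages of the per-frame fits; frame time `t_i`
#' maps to scaled time `(t_i - t_offset) / t0`. The fitted pair converts to
#' physical parameters via `f = Gamma B / L^3` and `eta = t0 B / L^4`.
#'
#' @param track a `contour_track` (see [gen_contour_track()]), or a list
#'   with `frames` (tibble: `t_s`, `xy`), `L_um`, `species_B`, optional
#'   logical `valid` mask.
#' @param library a [build_profile_library()] object.
#' @param n_points residual resampling resolution.
#' @param n_restarts perturbed restarts of the joint optimization.
#' @return object of class `profile_fit`: `gamma`, `t0_s`, `t_offset_s`,
#'   `rotation`, `translation_um`, `f_N_per_m`, `eta_SI` (and printed-unit
#'   copies), `residual_um2`, per-frame table, convergence flag.
#' @export
fit_global <- function(track, library, n_points = 64, n_restarts = 3) {
  valid <- if (!is.null(track$valid)) track$valid else
    rep(TRUE, nrow(track$frames))
  frames <- track$frames[valid, ]
  if (nrow(frames) < 3) abort("need at least 3 usable frames")
  L_um <- track$L_um
  B <- track$species_B

  per_frame <- list_rbind(lapply(frames$xy, function(xy) {
    fit_frame(xy, library, L_um, n_points = n_points)
  }))
  per_frame$t_s <- frames$t_s
  usable <- per_frame$converged & !per_frame$uninformative
  pf <- if (sum(usable) >= 2) per_frame[usable, ] else per_frame

  # seed: geometric-mean gamma; t0 from regressing fitted tau on frame time
  gamma0 <- exp(mean(log(pf$gamma)))
  sl <- tryCatch(coef(lm(t_scaled ~ t_s, data = pf)), error = function(e) NULL)
  t0_0 <- if (!is.null(sl) && is.finite(sl[2]) && sl[2] > 0) 1 / sl[2] else
    diff(range(frames$t_s)) / max(pf$t_scaled)
  toff0 <- min(
    if (!is.null(sl) && is.finite(sl[1])) -sl[1] * t0_0 else 0,
    min(frames$t_s)
  )
  frames_res <- lapply(frames$xy, resample_contour, n = n_points)
  start <- unname(c(log(gamma0), log(t0_0), toff0))
  dt_span <- max(diff(range(frames$t_s)), t0_0)

  # the buckling direction is chiral: optimize both mirror images and keep
  # the better branch
  best <- NULL
  mirrored <- FALSE
  for (mir in c(FALSE, TRUE)) {
    obj <- function(p) {
      global_residual(
        library, exp(p[1]), exp(p[2]), p[3], frames_res, frames$t_s,
        L_um, mir, n_points
      )
    }
    for (k in seq_len(n_restarts)) {
      st <- start
      if (k > 1) {
        st <- start + c(
          rnorm(1, 0, 0.05), rnorm(1, 0, 0.05),
          -abs(rnorm(1, 0, 0.02 * dt_span))
        )
      }
      o <- optim(st, obj,
        method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-14)
      )
      o <- optim(o$par, obj,
        method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-14)
      )
      if (is.null(best) || o$value < best$value) {
        best <- o
        mirrored <- mir
      }
    }
  }
  gamma <- min(max(exp(best$par[1]), min(library$gamma_grid)),
               max(library$gamma_grid))
  t0_s <- exp(best$par[2])
  t_offset <- best$par[3]

  # recover the shared transform at the optimum
  tr_hull <- library_time_range(library, gamma)
  tau <- pmin(pmax((frames$t_s - t_offset) / t0_s, 0), tr_hull[2])
  models <- lapply(tau, function(tt) {
    resample_contour(to_xy(library_phi(library, gamma, tt)) * L_um, n_points)
  })
  data_all <- do.call(rbind, frames_res)
  if (mirrored) data_all <- cbind(data_all[, 1], -data_all[, 2])
  pr <- procrustes_rigid(do.call(rbind, models), data_all)

  L_m <- um_to_m(L_um)
  edge <- gamma < 1.02 * min(library$gamma_grid) ||
    gamma > 0.98 * max(library$gamma_grid)
  if (edge) warn("fitted gamma is near the library edge")
  structure(
    list(
      gamma = gamma, t0_s = t0_s, t_offset_s = t_offset,
      mirrored = mirrored, rotation = pr$rotation,
      translation_um = pr$translation,
      residual_um2 = best$value,
      f_N_per_m = gamma * B / L_m^3,
      eta_SI = t0_s * B / L_m^4,
      f_nN_per_um = N_per_m_to_nN_per_um(gamma * B / L_m^3),
      eta_nNs_um2 = SI_to_nNs_per_um2(t0_s * B / L_m^4),
      L_um = L_um, species_B = B,
      per_frame = per_frame, converged = best$convergence == 0,
      edge = edge, n_frames = nrow(frames)
    ),
    class = "profile_fit"
  )
}

#' @export
print.profile_fit <- function(x, ...) {
  cat("Kirchhoff profile fit (", x$n_frames, " frames)\n", sep = "")
  cat(sprintf("  gamma = %.4g   t0 = %.4g s   offset = %.4g s\n",
              x$gamma, x$t0_s, x$t_offset_s))
  cat(sprintf("  f = %.3g nN/um   eta = %.3g nN s um^-2\n",
              x$f_nN_per_um, x$eta_nNs_um2))
  cat(sprintf("  mean residual = %.3g um^2\n", x$residual_um2))
  if (!is.null(x$bootstrap)) {
    cat("  bootstrap IQRs over", attr(x$bootstrap, "n_resamples"),
        "resamples available\n")
  }
  invisible(x)
}

#' @export
tidy.profile_fit <- function(x, ...) {
  tibble(
    term = c("gamma", "t0_s", "t_offset_s", "f_nN_per_um", "eta_nNs_um2"),
    estimate = c(x$gamma, x$t0_s, x$t_offset_s, x$f_nN_per_um,
                 x$eta_nNs_um2)
  )
}

#' @export
glance.profile_fit <- function(x, ...) {
  tibble(
    residual_um2 = x$residual_um2, n_frames = x$n_frames,
    converged = x$converged, edge = x$edge
  )
}

#' Coarse bootstrap of the global profile fit
#'
#' Repeats [fit_global()] on random frame subsets (default half of the
#' frames, drawn without replacement per resample) and reports
#' per-parameter interquartile ranges as spread estimates.
#'
#' @param track,library,n_points as in [fit_global()].
#' @param n_resamples number of refits.
#' @param subset_frac fraction of frames per resample.
#' @param seed integer seed.
#' @return the `profile_fit` of the full track with a `bootstrap` element:
#'   tibble of resample estimates plus an `iqr` attribute.
#' @export
bootstrap_global <- function(track, library, n_resamples = 20,
                             subset_frac = 0.5, n_points = 64, seed = NULL) {
  full <- fit_global(track, library, n_points = n_points)
  valid_idx <- which(if (!is.null(track$valid)) track$valid else
    rep(TRUE, nrow(track$frames)))
  n_take <- max(3, round(subset_frac * length(valid_idx)))
  with_seed(seed, {
    rows <- lapply(seq_len(n_resamples), function(i) {
      idx <- sort(sample(valid_idx, n_take))
      sub <- track
      sub$frames <- track$frames[idx, ]
      sub$valid <- rep(TRUE, length(idx))
      f <- tryCatch(
        fit_global(sub, library, n_points = n_points, n_restarts = 1),
        error = function(e) NULL
      )
      if (is.null(f)) return(NULL)
      tibble(
        resample = i, gamma = f$gamma, t0_s = f$t0_s,
        t_offset_s = f$t_offset_s, f_nN_per_um = f$f_nN_per_um,
        eta_nNs_um2 = f$eta_nNs_um2
      )
    })
    boot <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
    if (nrow(boot) < 2) abort("fewer than 2 successful resample fits")
    iqr <- vapply(
      boot[c("gamma", "t0_s", "f_nN_per_um", "eta_nNs_um2")],
      function(v) diff(quantile(v, c(0.25, 0.75))), numeric(1)
    )
    attr(boot, "n_resamples") <- n_resamples
    attr(boot, "subset_frac") <- subset_frac
    attr(boot, "iqr") <- iqr
    full$bootstrap <- boot
    full
  })
}

#' @export
autoplot.profile_fit <- function(object, track = NULL, library = NULL, ...) {
  if (is.null(track) || is.null(library)) {
    abort("supply the track and library used for the fit")
  }
  valid <- if (!is.null(track$valid)) track$valid else
    rep(TRUE, nrow(track$frames))
  frames <- track$frames[valid, ]
  tau <- (frames$t_s - object$t_offset_s) / object$t0_s
  R <- with(object, matrix(
    c(cos(rotation), sin(rotation), -sin(rotation), cos(rotation)), 2, 2
  ))
  df <- list_rbind(lapply(seq_len(nrow(frames)), function(i) {
    obs <- as.matrix(frames$xy[[i]])
    mod <- to_xy(library_phi(library, object$gamma, tau[i])) * object$L_um
    mod <- sweep(mod %*% t(R), 2, object$translation_um, "+")
    if (object$mirrored) obs <- cbind(obs[, 1], -obs[, 2])
    bind_rows(
      tibble(frame = i, kind = "observed", x = obs[, 1], y = obs[, 2]),
      tibble(frame = i, kind = "fitted", x = mod[, 1], y = mod[, 2])
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$kind)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~frame) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = NULL)
}
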