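# Micropipette three-point bending analysis.
#
# A filament resting across two support pillars a distance gap apart is
# deflected at mid-span by a calibrated micropipette force sensor. The
# pipette force follows Hooke's law (spring constant times deflection), the
# force-deflection relation of the filament is linear, and standard beam
# theory converts its slope to the bending modulus B = gap^3/48 * dP/dd.

#' Pipette force from Hooke's law
#'
#' @param deflection_um pipette deflection(s), um.
#' @param k_pipette_nN_um spring constant, nN/um (> 0).
#' @return force(s) in nN.
#' @examples
#' pipette_force(1, 9.5) # 9.5 nN
#' @export
pipette_force <- function(deflection_um, k_pipette_nN_um) {
  if (k_pipette_nN_um <= 0) abort("k_pipette must be > 0")
  k_pipette_nN_um * deflection_um
}

#' Least-squares slope of a force-deflection curve
#'
#' Fits force ~ deflection with an intercept (the intercept absorbs the
#' contact-point offset; only the slope enters the modulus). When a
#' `branch` factor distinguishing loading and unloading is supplied, a
#' hysteresis measure (relative loading/unloading slope difference) is
#' reported.
#'
#' @param force_nN forces, nN (>= 10 points).
#' @param deflection_um filament deflections, um.
#' @param branch optional character/factor of `"loading"`/`"unloading"`.
#' @return object of class `bending_slope`: `slope_nN_um`, `intercept_nN`,
#'   `r_squared`, `hysteresis` (NA without branches), `n`.
#' @export
fit_slope <- function(force_nN, deflection_um, branch = NULL) {
  if (length(force_nN) != length(deflection_um)) {
    abort("force and deflection must have equal length")
  }
  if (length(force_nN) < 10) abort("need at least 10 points")
  if (var(deflection_um) == 0) abort("deflection is constant: slope undefined")
  fit <- lm(force_nN ~ deflection_um)
  hysteresis <- NA_real_
  if (!is.null(branch)) {
    sl <- vapply(split(
      data.frame(f = force_nN, d = deflection_um), branch
    ), function(df) {
      if (nrow(df) < 2 || var(df$d) == 0) return(NA_real_)
      unname(coef(lm(f ~ d, df))[2])
    }, numeric(1))
    if (sum(is.finite(sl)) == 2) {
      hysteresis <- abs(diff(sl)) / mean(sl)
    }
  }
  structure(
    list(
      slope_nN_um = unname(coef(fit)[2]),
      intercept_nN = unname(coef(fit)[1]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      hysteresis = unname(hysteresis),
      n = length(force_nN)
    ),
    class = "bending_slope"
  )
}

#' @export
print.bending_slope <- function(x, ...) {
  cat(sprintf(
    "Bending slope: %.4g nN/um (R^2 = %.4f, n = %d)\n",
    x$slope_nN_um, x$r_squared, x$n
  ))
  if (is.finite(x$hysteresis)) {
    cat(sprintf("  hysteresis (rel. slope difference): %.3g\n", x$hysteresis))
  }
  invisible(x)
}

#' @export
tidy.bending_slope <- function(x, ...) {
  tibble(
    term = c("slope_nN_um", "intercept_nN"),
    estimate = c(x$slope_nN_um, x$intercept_nN)
  )
}

#' @export
glance.bending_slope <- function(x, ...) {
  tibble(r.squared = x$r_squared, hysteresis = x$hysteresis, n = x$n)
}

#' Bending modulus from a three-point bending slope
#'
#' B = gap^3 / 48 * dP/dd for a point load at mid-span between supports a
#' distance `gap` apart. Inputs are in printed units, the result in SI
#' (N m^2, printed as J m by [format_Jm()]).
#'
#' @param slope_nN_um force-deflection slope, nN/um (> 0).
#' @param pillar_gap_um support distance, um (> 0).
#' @return bending modulus in N m^2.
#' @examples
#' bending_modulus(13.13, 80) # ~1.4e-16
#' @export
bending_modulus <- function(slope_nN_um, pillar_gap_um) {
  if (any(slope_nN_um <= 0)) abort("slope must be > 0")
  if (any(pillar_gap_um <= 0)) abort("pillar gap must be > 0")
  gap_m <- um_to_m(pillar_gap_um)
  # dP/dd in SI: 1 nN/um = 1e-9 N / 1e-6 m = 1e-3 N/m
  slope_SI <- slope_nN_um * 1e-3
  gap_m^3 * slope_SI / 48
}

#' Run the full bending pipeline on one curve
#'
#' Converts pipette deflection to force, fits the slope and the modulus.
#'
#' @param curve tibble as from [gen_bending_curve()] or
#'   [read_bending_csv()]: needs `filament_deflection_um` and either
#'   `force_nN` or `pipette_deflection_um`.
#' @param k_pipette_nN_um spring constant used when force must be derived.
#' @param pillar_gap_um support distance, um.
#' @return object of class `bending_fit` with `B` (N m^2) and the slope fit.
#' @export
fit_bending <- function(curve, k_pipette_nN_um, pillar_gap_um) {
  force <- if ("force_nN" %in% names(curve)) {
    curve$force_nN
  } else {
    pipette_force(curve$pipette_deflection_um, k_pipette_nN_um)
  }
  branch <- if ("branch" %in% names(curve)) curve$branch else NULL
  sl <- fit_slope(force, curve$filament_deflection_um, branch)
  structure(
    list(
      B = bending_modulus(sl$slope_nN_um, pillar_gap_um),
      slope = sl, pillar_gap_um = pillar_gap_um,
      curve = as_tibble(curve)
    ),
    class = "bending_fit"
  )
}

#' @export
print.bending_fit <- function(x, ...) {
  cat("Three-point bending fit\n")
  cat("  B =", format_Jm(x$B), " (slope", format(x$slope$slope_nN_um,
    digits = 4
  ), "nN/um over", x$pillar_gap_um, "um gap)\n")
  invisible(x)
}

#' @export
tidy.bending_fit <- function(x, ...) {
  tibble(
    term = c("B_Nm2", "slope_nN_um", "intercept_nN"),
    estimate = c(x$B, x$slope$slope_nN_um, x$slope$intercept_nN)
  )
}

#' @export
glance.bending_fit <- function(x, ...) {
  tibble(
    B_Nm2 = x$B, r.squared = x$slope$r_squared,
    hysteresis = x$slope$hysteresis, n = x$slope$n
  )
}

#' @export
autoplot.bending_fit <- function(object, ...) {
  df <- object$curve
  df$force <- if ("force_nN" %in% names(df)) df$force_nN else
    pipette_force(df$pipette_deflection_um, 1)
  ggplot2::ggplot(df, ggplot2::aes(.data$filament_deflection_um,
                                   .data$force)) +
    ggplot2::geom_point(ggplot2::aes(
      colour = if ("branch" %in% names(df)) .data$branch else NULL
    ), alpha = 0.7) +
    ggplot2::geom_abline(
      intercept = object$slope$intercept_nN,
      slope = object$slope$slope_nN_um, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "filament deflection d (um)", y = "force P (nN)",
      colour = NULL,
      title = sprintf("Three-point bending: B = %s", format_Jm(object$B))
    )
}

#' Box statistics of an ensemble of bending moduli
#'
#' Quartiles by linear interpolation between order statistics; whiskers
#' reach the last measurement within one inter-quartile distance of the box
#' limit (whisker length 1 x IQR).
#'
#' @param B_values numeric vector of moduli (>= 2 values).
#' @return one-row tibble with `q1`, `median`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `n`.
#' @export
summarize_moduli <- function(B_values) {
  if (length(B_values) < 2) abort("need at least 2 values")
  q <- quantile(B_values, c(0.25, 0.5, 0.75), type = 7)
  iqr <- q[3] - q[1]
  lo_candidates <- B_values[B_values >= q[1] - iqr]
  hi_candidates <- B_values[B_values <= q[3] + iqr]
  tibble(
    q1 = unname(q[1]), median = unname(q[2]), q3 = unname(q[3]),
    whisker_lo = min(lo_candidates), whisker_hi = max(hi_candidates),
    n = length(B_values)
  )
}
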