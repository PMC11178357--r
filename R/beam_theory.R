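# Linear stability of the self-propelled elastica.
#
# A gliding filament of bending modulus B, pushed by a tangential force
# density f against an obstacle that pins its head, is neutrally stable below
# a critical contour length and buckles above it. In scaled coordinates
# (arclength s in [0,1], time in units t0 = L^4 eta / B) the linearized
# curvature equation for stationary rotor solutions phi(s,t) = phi(s) + w t is
#
#     kappa'' + Gamma (1 - s) kappa + w s = 0,
#
# with Gamma = L^3 f / B and boundary conditions
# kappa(0) = kappa(1) = kappa'(1) = 0. The smallest Gamma admitting a
# nontrivial solution is the buckling threshold; it is also the smallest
# positive root of a closed-form combination of generalized hypergeometric
# functions, which gives an independent route to the same constant.

# cache for expensive constants
the <- new.env(parent = emptyenv())

# ---- generalized hypergeometric series -------------------------------------

#' Generalized hypergeometric function by direct series summation
#'
#' Evaluates pFq(upper; lower; z) by summing the power series with the term
#' recurrence t_{n+1} = t_n * prod(upper + n) / prod(lower + n) * z / (n + 1).
#' The arguments arising in the buckling threshold are O(-3.4), for which the
#' series converges rapidly.
#'
#' @param upper numeric vector of upper parameters (may be empty).
#' @param lower numeric vector of lower parameters (none may be a
#'   non-positive integer).
#' @param z argument.
#' @param tol stop when `|term| <= tol * |sum|`.
#' @param max_terms series length guard.
#' @return numeric scalar.
#' @examples
#' pfq(numeric(0), 2 / 3, -1)      # 0F1(; 2/3; -1)
#' pfq(1 / 3, c(2 / 3, 4 / 3), -1) # 1F2(1/3; 2/3, 4/3; -1)
#' @export
pfq <- function(upper, lower, z, tol = 1e-15, max_terms = 500L) {
  if (any(lower <= 0 & lower == round(lower))) {
    abort("lower parameters must not be non-positive integers")
  }
  term <- 1
  total <- 1
  for (n in 0:(max_terms - 1L)) {
    term <- term * (if (length(upper)) prod(upper + n) else 1) /
      prod(lower + n) * z / (n + 1)
    total <- total + term
    if (abs(term) <= tol * abs(total)) return(total)
  }
  warn("pfq: series not converged to tol; returning partial sum")
  total
}

# residual of the closed-form threshold condition at load k
threshold_equation <- function(k) {
  z <- -k / 9
  2 * k * pfq(numeric(0), 4 / 3, z) * pfq(1 / 3, c(2 / 3, 4 / 3), z) +
    pfq(numeric(0), 2 / 3, z) * (2 - k * pfq(2 / 3, c(4 / 3, 5 / 3), z)) - 2
}

#' Buckling threshold from the hypergeometric root condition
#'
#' The critical activity coefficient of the pinned-head, free-tail,
#' tangentially propelled elastica is the smallest strictly positive root of
#' a combination of generalized hypergeometric functions evaluated at -k/9.
#' k = 0 is a trivial root (all pFq are 1 there) and is excluded by
#' bracketing the search away from zero.
#'
#' @param interval search interval; must bracket a sign change.
#' @param tol root tolerance passed to [stats::uniroot()].
#' @return the threshold, approximately 30.5722.
#' @examples
#' hypergeom_threshold()
#' @export
hypergeom_threshold <- function(interval = c(1, 100), tol = 1e-12) {
  if (!is.null(the$hypergeom_root) && identical(interval, c(1, 100))) {
    return(the$hypergeom_root)
  }
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 64))
  vals <- vapply(grid, threshold_equation, numeric(1))
  sgn <- which(diff(sign(vals)) != 0)
  if (!length(sgn)) {
    abort(sprintf(
      "no sign change of the threshold equation in (%g, %g)",
      interval[1], interval[2]
    ))
  }
  i <- sgn[1]
  root <- uniroot(threshold_equation, c(grid[i], grid[i + 1]), tol = tol)$root
  if (identical(interval, c(1, 100))) the$hypergeom_root <- root
  root
}

# internal: cached threshold constant used wherever the closed-form prefactor
# 30.5722 appears in physical formulas
gamma_c <- function() hypergeom_threshold()

# ---- shooting solver for the linearized boundary-value problem -------------

#' Boundary condition sets for the linear buckling problem
#'
#' `pinned_free_tangential` is the gliding filament: head pinned by the
#' obstacle, tail free, propulsion tangential; conditions
#' kappa(0) = kappa(1) = kappa'(1) = 0 on the curvature, with the rotation
#' rate w entering as a third unknown. `clamped_free_gravity` is Euler's
#' heavy column: slope u clamped to zero at the base, zero bending moment
#' (u'(1) = 0) at the free top, no rotation unknown.
#'
#' @param name one of `"pinned_free_tangential"`, `"clamped_free_gravity"`.
#' @return an object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(name = c(
                                  "pinned_free_tangential",
                                  "clamped_free_gravity"
                                )) {
  name <- match.arg(name)
  bc_list <- switch(name,
    pinned_free_tangential = c("kappa(0)=0", "kappa(1)=0", "kappa'(1)=0"),
    clamped_free_gravity = c("u(0)=0", "u'(1)=0")
  )
  structure(list(name = name, bc_list = bc_list), class = "boundary_conditions")
}

# Integrate y'' = -Gamma (1 - s) y - w s from s=0 to s=1 for initial
# conditions (y0, dy0) and forcing weight w (0 for homogeneous solutions,
# 1 for the particular rotor solution). Returns the deSolve matrix over a
# dense s grid.
integrate_mode <- function(gamma, y0, dy0, w, s = seq(0, 1, length.out = 201)) {
  rhs <- function(s, y, parms) {
    list(c(y[2], -gamma * (1 - s) * y[1] - w * s))
  }
  deSolve::ode(c(y0, dy0), s, rhs,
    parms = NULL, method = "lsoda",
    rtol = 1e-10, atol = 1e-12
  )
}

# Boundary determinant of the linear problem at activity gamma.
# pinned_free_tangential: unknowns (c1, c2, w), rows kappa(0), kappa(1),
# kappa'(1); clamped_free_gravity: unknowns (c1, c2), rows u(0), u'(1).
boundary_system <- function(gamma, bcs, s = c(0, 1)) {
  h1 <- integrate_mode(gamma, 1, 0, 0, s)
  h2 <- integrate_mode(gamma, 0, 1, 0, s)
  last <- nrow(h1)
  if (bcs$name == "pinned_free_tangential") {
    p <- integrate_mode(gamma, 0, 0, 1, s)
    rbind(
      c(h1[1, 2], h2[1, 2], p[1, 2]),
      c(h1[last, 2], h2[last, 2], p[last, 2]),
      c(h1[last, 3], h2[last, 3], p[last, 3])
    )
  } else {
    rbind(
      c(h1[1, 2], h2[1, 2]),
      c(h1[last, 3], h2[last, 3])
    )
  }
}

#' Critical load of the linearized buckling problem by shooting
#'
#' Builds the general solution of the linearized curvature equation as a
#' combination of two homogeneous initial-value solutions (plus, for the
#' pinned-free set, a particular solution forced by the rotation rate w),
#' assembles the homogeneous boundary system in the free coefficients, and
#' locates the smallest Gamma at which its determinant vanishes by a log-grid
#' scan followed by [stats::uniroot()] refinement. The null-space mode is
#' returned normalized to max |kappa| = 1 with kappa'(0) > 0.
#'
#' @param bcs a [boundary_conditions()] object (or its name).
#' @param interval Gamma scan range.
#' @param n_mode number of arclength points for the returned mode.
#' @return an object of class `critical_point`: a list with `gamma_c`,
#'   `omega` (0 for the clamped set), `mode` (tibble with columns `s`,
#'   `kappa`) and `bcs`.
#' @examples
#' linear_threshold_numeric("pinned_free_tangential")$gamma_c # ~30.5722
#' linear_threshold_numeric("clamped_free_gravity")$gamma_c # ~7.837
#' @export
linear_threshold_numeric <- function(bcs = "pinned_free_tangential",
                                     interval = c(1, 100), n_mode = 201) {
  if (is.character(bcs)) bcs <- boundary_conditions(bcs)
  stopifnot(inherits(bcs, "boundary_conditions"))
  detfun <- function(g) det(boundary_system(g, bcs))
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 64))
  vals <- vapply(grid, detfun, numeric(1))
  sgn <- which(diff(sign(vals)) != 0)
  if (!length(sgn)) {
    abort(sprintf(
      "no sign change of the boundary determinant in Gamma range (%g, %g)",
      interval[1], interval[2]
    ))
  }
  i <- sgn[1]
  gc <- uniroot(detfun, c(grid[i], grid[i + 1]), tol = 1e-12)$root

  # null vector of the boundary system -> mode coefficients
  M <- boundary_system(gc, bcs)
  sv <- svd(M)
  coefs <- sv$v[, ncol(M)]
  s <- seq(0, 1, length.out = n_mode)
  h1 <- integrate_mode(gc, 1, 0, 0, s)
  h2 <- integrate_mode(gc, 0, 1, 0, s)
  if (bcs$name == "pinned_free_tangential") {
    p <- integrate_mode(gc, 0, 0, 1, s)
    kappa <- coefs[1] * h1[, 2] + coefs[2] * h2[, 2] + coefs[3] * p[, 2]
    dkappa0 <- coefs[1] * h1[1, 3] + coefs[2] * h2[1, 3] + coefs[3] * p[1, 3]
    omega <- coefs[3]
  } else {
    kappa <- coefs[1] * h1[, 2] + coefs[2] * h2[, 2]
    dkappa0 <- coefs[1] * h1[1, 3] + coefs[2] * h2[1, 3]
    omega <- 0
  }
  scl <- max(abs(kappa))
  sgn_fix <- if (dkappa0 < 0) -1 else 1
  kappa <- sgn_fix * kappa / scl
  omega <- sgn_fix * omega / scl
  structure(
    list(
      gamma_c = gc, omega = omega,
      mode = tibble(s = s, kappa = kappa), bcs = bcs
    ),
    class = "critical_point"
  )
}

#' @export
print.critical_point <- function(x, ...) {
  cat("Critical point (", x$bcs$name, ")\n", sep = "")
  cat("  gamma_c =", format(x$gamma_c, digits = 8), "\n")
  cat("  omega   =", format(x$omega, digits = 6), "\n")
  invisible(x)
}

# ---- physical-unit relations -----------------------------------------------

#' Critical self-buckling length
#'
#' Lc = (k B / f)^(1/3) with k the buckling threshold (~30.5722): a gliding
#' filament longer than Lc buckles on head-on collision.
#'
#' @param B bending modulus, N m^2 (> 0).
#' @param f active force density, N/m (> 0).
#' @return critical length in m.
#' @examples
#' m_to_um(critical_length(1.4e-16, 1e-3)) # ~162 um
#' @export
critical_length <- function(B, f) {
  if (any(B <= 0)) abort("B must be > 0")
  if (any(f <= 0)) abort("f must be > 0")
  (gamma_c() * B / f)^(1 / 3)
}

#' Active force density from an observed critical length
#'
#' Inverts [critical_length()]: f = k B / Lc^3.
#'
#' @param B bending modulus, N m^2 (> 0).
#' @param Lc critical length, m (> 0).
#' @return force density in N/m.
#' @examples
#' N_per_m_to_nN_per_um(force_from_critical_length(1.4e-16, 161e-6)) # ~1.0
#' @export
force_from_critical_length <- function(B, Lc) {
  if (any(B <= 0)) abort("B must be > 0")
  if (any(Lc <= 0)) abort("Lc must be > 0")
  gamma_c() * B / Lc^3
}

#' Velocity-dependent critical length under isotropic friction
#'
#' With overdamped co-linear friction the propulsion density is f = eta v0,
#' so Lc(v0) = (eta v0 / (k B))^(-1/3), identical to
#' `critical_length(B, eta * v0)`.
#'
#' @param B bending modulus, N m^2 (> 0).
#' @param eta friction coefficient, N s m^-2 (> 0).
#' @param v0 free-gliding speed, m/s (> 0).
#' @return critical length in m.
#' @examples
#' m_to_um(critical_length_velocity(1.4e-16, 600, 2e-6)) # ~153 um
#' @export
critical_length_velocity <- function(B, eta, v0) {
  if (any(B <= 0) || any(eta <= 0) || any(v0 <= 0)) {
    abort("all arguments must be > 0")
  }
  (eta * v0 / (gamma_c() * B))^(-1 / 3)
}
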