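# Unit conversions between SI (used internally by all theory code) and the
# "printed" microscopy units (um, nN/um, nN s um^-2). Conversions are applied
# exactly once, at the I/O boundary; everything downstream of these helpers is
# SI.

#' Unit conversions between SI and microscopy units
#'
#' Internally all mechanics is done in SI: lengths in m, bending modulus B in
#' N m^2 (equivalently J m), force density f in N/m, friction coefficient eta
#' in N s m^-2. Experimental tables use um, nN/um and nN s um^-2. One
#' nN/um = 1e-3 N/m; one nN s um^-2 = 1e3 N s m^-2; one um = 1e-6 m.
#'
#' @param x numeric vector in the source unit.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname units
#' @export
m_to_um <- function(x) x * 1e6

#' @rdname units
#' @export
nN_per_um_to_N_per_m <- function(x) x * 1e-3

#' @rdname units
#' @export
N_per_m_to_nN_per_um <- function(x) x * 1e3

#' @rdname units
#' @export
nNs_per_um2_to_SI <- function(x) x * 1e3

#' @rdname units
#' @export
SI_to_nNs_per_um2 <- function(x) x * 1e-3

#' Format / parse a bending modulus in printed units
#'
#' The experimental literature quotes bending moduli as multiples of
#' 1e-16 J m. `format_Jm()` renders an SI value (N m^2 == J m) that way and
#' `parse_Jm()` inverts the rendering exactly.
#'
#' @param B bending modulus in N m^2.
#' @param digits significant digits to print.
#' @return `format_Jm()` a character scalar; `parse_Jm()` a numeric scalar.
#' @examples
#' format_Jm(1.4e-16)
#' parse_Jm(format_Jm(1.4e-16))
#' @export
format_Jm <- function(B, digits = 3) {
  stopifnot(is.numeric(B), length(B) == 1L)
  sprintf("%se-16 J m", trimws(formatC(B / 1e-16, digits = digits,
                                       format = "g")))
}

#' @rdname format_Jm
#' @param x character as produced by `format_Jm()`.
#' @export
parse_Jm <- function(x) {
  m <- regmatches(x, regexec("^([0-9.eE+-]+)e-16 J m$", x))[[1]]
  if (length(m) != 2L) abort("not a recognised 'Xe-16 J m' string")
  as.numeric(m[2]) * 1e-16
}

#' Material and propulsion parameters of a gliding filament
#'
#' A validated container for the elastica parameters in SI units: bending
#' modulus `B` (N m^2), tangential active force density `f` (N/m), isotropic
#' friction coefficient `eta` (N s m^-2) and contour length `L` (m).
#'
#' @param B bending modulus, N m^2 (> 0).
#' @param f active force density, N/m (>= 0).
#' @param eta friction coefficient, N s m^-2 (>= 0).
#' @param L contour length, m (> 0).
#' @return an object of class `elastica_params` (a named list).
#' @examples
#' elastica_params(B = 1.4e-16, f = 1e-3, eta = 600, L = 200e-6)
#' @export
elastica_params <- function(B, f = 0, eta = 0, L = 1) {
  stopifnot(is.numeric(B), is.numeric(f), is.numeric(eta), is.numeric(L))
  if (B <= 0) abort("B must be > 0")
  if (L <= 0) abort("L must be > 0")
  if (f < 0) abort("f must be >= 0")
  if (eta < 0) abort("eta must be >= 0")
  structure(list(B = B, f = f, eta = eta, L = L), class = "elastica_params")
}

#' @export
print.elastica_params <- function(x, ...) {
  cat("Elastica parameters\n")
  cat("  B   =", format_Jm(x$B), "\n")
  cat("  f   =", N_per_m_to_nN_per_um(x$f), "nN/um\n")
  cat("  eta =", SI_to_nNs_per_um2(x$eta), "nN s um^-2\n")
  cat("  L   =", m_to_um(x$L), "um\n")
  invisible(x)
}

#' Dimensionless activity coefficient
#'
#' Gamma = L^3 f / B, the single control parameter of the scaled buckling
#' problem (a flexure number): filaments buckle head-on when Gamma exceeds
#' the critical value returned by [hypergeom_threshold()].
#'
#' @param params an [elastica_params()] object.
#' @return dimensionless Gamma.
#' @export
activity_coefficient <- function(params) {
  stopifnot(inherits(params, "elastica_params"))
  params$L^3 * params$f / params$B
}
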