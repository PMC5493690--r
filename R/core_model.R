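#' Two-level description of an odorant's contorsional mode
#'
#' Non-planar odorants carry a contorsional vibration in which an atom group
#' oscillates between the wells of an asymmetric double-well potential.  When
#' the barrier is high compared to the well-bottom frequency the mode truncates
#' to a two-level system spanned by the localised handed states \eqn{|L\rangle}
#' and \eqn{|R\rangle}, with Hamiltonian
#' \eqn{H = -\omega_z \sigma_z + \omega_x \sigma_x} in frequency units.
#'
#' @param omega_x Tunneling frequency (Hz), non-negative.  Sets the rate of
#'   coherent inter-conversion between the handed states.
#' @param omega_z Asymmetry frequency (Hz), non-negative.  Overall measure of
#'   the chiral (parity-odd) interactions that bias one well.
#' @param warn If `TRUE` (default), warn when either frequency exceeds the
#'   physically motivated maximum of \eqn{10^{12}} Hz.
#'
#' @return An object of class `odorant_two_level` with fields `omega_x`,
#'   `omega_z`, the mixing angle `theta` \eqn{= \frac12\arctan(\omega_x/\omega_z)}
#'   (rad) and the level `splitting` \eqn{2\sqrt{\omega_x^2+\omega_z^2}} (Hz).
#' @examples
#' od <- odorant_two_level(1e6, 1e9)
#' od$theta
#' @export
odorant_two_level <- function(omega_x, omega_z, warn = TRUE) {
  stopifnot(length(omega_x) == 1L, length(omega_z) == 1L,
            is.finite(omega_x), is.finite(omega_z))
  if (omega_x < 0 || omega_z < 0)
    stop("omega_x and omega_z must be non-negative frequencies (Hz)")
  if (omega_x == 0 && omega_z == 0)
    stop("degenerate odorant: omega_x and omega_z cannot both be zero")
  if (warn && (omega_x > .omega_physical_max || omega_z > .omega_physical_max))
    warning("omega_x or omega_z exceeds the physical maximum of about 1e12 Hz ",
            "expected for molecular contorsional modes", call. = FALSE)
  structure(
    list(omega_x = omega_x, omega_z = omega_z,
         theta = mixing_angle(omega_x, omega_z),
         splitting = 2 * sqrt(omega_x^2 + omega_z^2)),
    class = "odorant_two_level")
}

#' @export
print.odorant_two_level <- function(x, ...) {
  cat("Odorant two-level contorsional mode\n")
  cat(sprintf("  omega_x (tunneling): %.6g Hz\n", x$omega_x))
  cat(sprintf("  omega_z (asymmetry): %.6g Hz\n", x$omega_z))
  cat(sprintf("  mixing angle theta : %.6g rad\n", x$theta))
  cat(sprintf("  level splitting    : %.6g Hz\n", x$splitting))
  invisible(x)
}

#' Odorant mixing angle
#'
#' Angle \eqn{\theta = \frac{1}{2}\arctan(\omega_x/\omega_z)} rotating the
#' handed states into the energy eigenstates
#' \eqn{|E_1\rangle = \sin\theta|L\rangle + \cos\theta|R\rangle},
#' \eqn{|E_2\rangle = \cos\theta|L\rangle - \sin\theta|R\rangle}.
#'
#' @param omega_x Tunneling frequency, Hz (non-negative).
#' @param omega_z Asymmetry frequency, Hz (non-negative).
#' @return Mixing angle in radians, in \eqn{[0, \pi/4]}; the symmetric-well
#'   limit \eqn{\omega_z = 0} returns \eqn{\pi/4}.
#' @export
mixing_angle <- function(omega_x, omega_z) {
  stopifnot(is.numeric(omega_x), is.numeric(omega_z))
  if (any(omega_x < 0) || any(omega_z < 0))
    stop("frequencies must be non-negative")
  if (any(omega_x == 0 & omega_z == 0))
    stop("mixing angle undefined when omega_x and omega_z are both zero")
  ifelse(omega_z == 0, pi / 4, 0.5 * atan(omega_x / omega_z))
}

#' Double-well geometry of the contorsional potential
#'
#' Holds the geometric parameters of the asymmetric double well from which the
#' tunneling frequency can be estimated semiclassically.  The two-level
#' truncation used throughout the package requires a high barrier,
#' \eqn{V_0 \gg \omega_0}; the constructor records a validity flag using the
#' default check \eqn{V_0/\omega_0 \ge 5}.
#'
#' @param V0 Barrier height, expressed in the same frequency units as
#'   `omega_0` (non-negative).
#' @param omega_0 Vibration frequency at the bottom of each well (positive).
#' @param M Molecular mass (natural units; see Details).
#' @param q0 Distance between the two potential minima (natural units).
#' @param A,B Dimensionless prefactors of the WKB estimate, both defaulting
#'   to 1 as is customary for generic double wells.
#'
#' @details The WKB expression implemented by [wkb_tunneling_frequency()] is
#'   used literally in natural units (\eqn{\hbar = 1}); it is not
#'   dimensionally homogeneous if `M` and `q0` are fed in SI units, so the
#'   caller owns any unit conversion.
#'
#' @return Object of class `double_well_geometry`, with logical field
#'   `two_level_valid`.
#' @export
double_well_geometry <- function(V0, omega_0, M, q0, A = 1, B = 1) {
  stopifnot(is.finite(V0), is.finite(omega_0), is.finite(M), is.finite(q0))
  if (V0 < 0) stop("barrier height V0 must be non-negative")
  if (omega_0 <= 0) stop("well-bottom frequency omega_0 must be positive")
  structure(
    list(V0 = V0, omega_0 = omega_0, M = M, q0 = q0, A = A, B = B,
         two_level_valid = (V0 / omega_0) >= 5),
    class = "double_well_geometry")
}

#' WKB estimate of the tunneling frequency
#'
#' Semiclassical estimate
#' \eqn{\omega_x = A q_0 \sqrt{M \omega_0}\, e^{-B V_0/\omega_0}} for the
#' splitting of the lowest doublet of a double well: exponentially suppressed
#' in the barrier height and scaling as \eqn{\sqrt{M}} in the mass.
#'
#' @param geometry A [double_well_geometry()].
#' @return Tunneling frequency in the units implied by the inputs (natural
#'   units, see [double_well_geometry()]).
#' @export
wkb_tunneling_frequency <- function(geometry) {
  stopifnot(inherits(geometry, "double_well_geometry"))
  with(geometry, A * q0 * sqrt(M * omega_0) * exp(-B * V0 / omega_0))
}

#' Electronic parameters of the donor-acceptor pair
#'
#' Site energies and couplings of the electron that tunnels through the
#' odorant: the donor-acceptor gap \eqn{\varepsilon}, the hopping strength
#' \eqn{\Delta}, and the odorant couplings \eqn{\gamma_D}, \eqn{\gamma_A}.
#'
#' @param eps Donor-acceptor gap (Hz).  May be omitted when both site energies
#'   are supplied, in which case `eps = eps_D - eps_A`.
#' @param delta Hopping strength \eqn{\Delta} (Hz).
#' @param gamma_D,gamma_A Couplings of the donor and acceptor sites to the
#'   odorant's contorsional mode (Hz); sign conventions follow
#'   [default_electronic_parameters()].
#' @param eps_D,eps_A Optional site energies (Hz).
#' @return Object of class `electronic_parameters`.
#' @seealso [default_electronic_parameters()] for the standard
#'   odorant-consistent parameterisation.
#' @export
electronic_parameters <- function(eps = NULL, delta, gamma_D, gamma_A,
                                  eps_D = NULL, eps_A = NULL) {
  if (is.null(eps)) {
    if (is.null(eps_D) || is.null(eps_A))
      stop("supply either eps or both eps_D and eps_A")
    eps <- eps_D - eps_A
  } else if (!is.null(eps_D) && !is.null(eps_A) &&
             !isTRUE(all.equal(eps, eps_D - eps_A))) {
    stop("eps inconsistent with eps_D - eps_A")
  }
  stopifnot(is.finite(eps), is.finite(delta), is.finite(gamma_D),
            is.finite(gamma_A))
  structure(
    list(eps = eps, delta = delta, gamma_D = gamma_D, gamma_A = gamma_A,
         eps_D = eps_D, eps_A = eps_A),
    class = "electronic_parameters")
}

#' @export
print.electronic_parameters <- function(x, ...) {
  cat("Electronic parameters (Hz)\n")
  cat(sprintf("  eps     : %.6g\n  delta   : %.6g\n", x$eps, x$delta))
  cat(sprintf("  gamma_D : %.6g\n  gamma_A : %.6g\n", x$gamma_D, x$gamma_A))
  invisible(x)
}

#' Default odorant-consistent electronic parameters
#'
#' Energy conservation ties the donor-acceptor gap to the odorant's natural
#' frequency, \eqn{\varepsilon \simeq \sqrt{\omega_x^2+\omega_z^2}}; the
#' hopping is weak, \eqn{\Delta = 0.01\,\varepsilon}; and the Huang-Rhys-type
#' couplings are antisymmetric,
#' \eqn{\gamma_D = -\gamma_A = 0.1\,\varepsilon}.
#'
#' @param odorant An [odorant_two_level()].
#' @return An [electronic_parameters()] object.
#' @export
default_electronic_parameters <- function(odorant) {
  stopifnot(inherits(odorant, "odorant_two_level"))
  om <- sqrt(odorant$omega_x^2 + odorant$omega_z^2)
  electronic_parameters(eps = om, delta = 0.01 * om,
                        gamma_D = 0.1 * om, gamma_A = -0.1 * om)
}

#' Check the weak-coupling validity condition
#'
#' The perturbative (polaron-frame) rates require the hopping \eqn{\Delta} to
#' sit at least two orders of magnitude below the bath cutoff \eqn{\lambda}.
#'
#' @param params An [electronic_parameters()].
#' @param spectrum A [bath_spectrum()].
#' @return `TRUE` when `delta <= 0.01 * cutoff`.
#' @export
weak_coupling_ok <- function(params, spectrum) {
  stopifnot(inherits(params, "electronic_parameters"),
            inherits(spectrum, "bath_spectrum"))
  params$delta <= 0.01 * spectrum$cutoff
}

#' Polaron shifts of the donor and acceptor energies
#'
#' The polaron transformation that diagonalises the unperturbed Hamiltonian
#' shifts the two site energies by
#' \deqn{\eta_A = -\frac{\omega_z}{2}\cos\left\{\arctan\frac{\omega_x+\gamma_A}{\omega_z}\right\},\quad
#'       \eta_D = -\frac{\omega_z}{2}\cos\left\{\arctan\frac{\omega_x-\gamma_D}{\omega_z}\right\}.}
#' Both shifts lie in \eqn{[-\omega_z/2, 0]}; they coincide whenever
#' \eqn{\omega_x - \gamma_D = \omega_x + \gamma_A} (in particular for the
#' antisymmetric default couplings).
#'
#' @param odorant An [odorant_two_level()].
#' @param params An [electronic_parameters()].
#' @return Named numeric vector `c(eta_D, eta_A)` in Hz.
#' @export
polaron_shifts <- function(odorant, params) {
  stopifnot(inherits(odorant, "odorant_two_level"),
            inherits(params, "electronic_parameters"))
  wz <- odorant$omega_z
  if (wz == 0) return(c(eta_D = 0, eta_A = 0))  # cos(arctan(Inf)) -> 0 limit
  c(eta_D = -(wz / 2) * cos(atan((odorant$omega_x - params$gamma_D) / wz)),
    eta_A = -(wz / 2) * cos(atan((odorant$omega_x + params$gamma_A) / wz)))
}

#' Polaron mixing angle
#'
#' Dressed rotation angle
#' \deqn{\upsilon = \frac12\left[\arctan\frac{\omega_x+\gamma_A}{\omega_z} +
#'       \arctan\frac{\omega_x-\gamma_D}{\omega_z}\right]}
#' entering the inelastic rate formulas.  For vanishing odorant couplings it
#' reduces to \eqn{\arctan(\omega_x/\omega_z) = 2\theta}.
#'
#' @inheritParams polaron_shifts
#' @return Angle in radians.
#' @export
polaron_mixing_angle <- function(odorant, params) {
  stopifnot(inherits(odorant, "odorant_two_level"),
            inherits(params, "electronic_parameters"))
  wz <- odorant$omega_z
  half_atan <- function(x) {
    if (wz == 0) {
      if (x == 0) 0 else sign(x) * pi / 2
    } else atan(x / wz)
  }
  0.5 * (half_atan(odorant$omega_x + params$gamma_A) +
         half_atan(odorant$omega_x - params$gamma_D))
}

#' Polaron frame of an odorant-electron pair
#'
#' Bundles the shifted energies and the dressed mixing angle consumed by every
#' rate formula.
#'
#' @inheritParams polaron_shifts
#' @return Object of class `polaron_frame` with fields `eta_D`, `eta_A` (Hz)
#'   and `upsilon` (rad).
#' @export
polaron_frame <- function(odorant, params) {
  eta <- polaron_shifts(odorant, params)
  structure(
    list(eta_D = unname(eta["eta_D"]), eta_A = unname(eta["eta_A"]),
         upsilon = polaron_mixing_angle(odorant, params)),
    class = "polaron_frame")
}

#' @export
print.polaron_frame <- function(x, ...) {
  cat("Polaron frame\n")
  cat(sprintf("  eta_D   : %.6g Hz\n  eta_A   : %.6g Hz\n", x$eta_D, x$eta_A))
  cat(sprintf("  upsilon : %.6g rad\n", x$upsilon))
  invisible(x)
}

#' Polaron-frame propagator matrix of the odorant
#'
#' The 2x2 matrix \eqn{\Omega(t)} whose elements weight the odorant transition
#' amplitudes in the second-order transfer probability:
#' \deqn{\Omega_{11}(t) = \Omega_{22}(-t) = \cos\upsilon\, e^{-it(\eta_2-\eta_1)},\qquad
#'       \Omega_{12}(t) = -\Omega_{21}(-t) = \sin\upsilon\, e^{-it(\eta_1+\eta_2)},}
#' with \eqn{(\eta_1,\eta_2) = (\eta_A,\eta_D)}.  Columns are normalised,
#' \eqn{|\Omega_{11}|^2 + |\Omega_{21}|^2 = 1}, for all `t`.
#'
#' @param t Time (s).
#' @inheritParams polaron_shifts
#' @param frame Optional precomputed [polaron_frame()].
#' @return A 2x2 complex matrix.
#' @export
omega_matrix <- function(t, odorant, params, frame = polaron_frame(odorant, params)) {
  stopifnot(inherits(frame, "polaron_frame"), length(t) == 1L, is.finite(t))
  e1 <- .eta1(frame); e2 <- .eta2(frame)
  cu <- cos(frame$upsilon); su <- sin(frame$upsilon)
  # phases x*t with x in Hz: times are conjugate to the Hz energy scale
  # (hbar = 1 convention used throughout the dynamical integrals)
  ph_diff <- exp(-1i * t * (e2 - e1))
  ph_sum  <- exp(-1i * t * (e1 + e2))
  matrix(c(cu * ph_diff, -su * Conj(ph_sum),
           su * ph_sum,   cu * Conj(ph_diff)),
         nrow = 2, ncol = 2)
}
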