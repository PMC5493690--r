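#' Effective collisional mass
#'
#' Harmonic (reduced) combination \eqn{m = \mu m_t/(\mu + m_t)} of the
#' odorant's reduced mass \eqn{\mu} and the average mass \eqn{m_t} of the
#' environment molecules colliding with it; symmetric in its arguments and
#' never exceeding the smaller of the two.
#'
#' @param mu Reduced mass of the odorant's contorsional mode, kg.
#' @param m_t Average collision-partner mass, kg.
#' @return Effective mass, kg.
#' @export
effective_mass <- function(mu, m_t) {
  stopifnot(is.numeric(mu), is.numeric(m_t))
  if (any(mu <= 0) || any(m_t <= 0)) stop("masses must be positive")
  mu * m_t / (mu + m_t)
}

#' Critical pressure for tunneling suppression
#'
#' Pressure at which environmental collisions decohere the contorsional mode
#' strongly enough to freeze the tunneling:
#' \deqn{P_{cr} = \frac{\sqrt{2\,\omega_x^2\, m\, k_B T}}{\sigma},}
#' with \eqn{m} the effective mass from [effective_mass()] and \eqn{\sigma}
#' the decoherence cross-section.  Monotone increasing in the effective mass
#' and in \eqn{\sqrt{T}}, which is the root of the isotope prediction:
#' heavier isotopes raise \eqn{P_{cr}}.
#'
#' @param omega_x Tunneling frequency, Hz (ordinary frequency; no \eqn{2\pi}).
#' @param m_eff Effective mass, kg.
#' @param temperature Temperature, K.
#' @param sigma Decoherence cross-section, m^2.  A hard-sphere estimate for a
#'   small odorant at room temperature is about 150 Bohr-radii squared
#'   (`150 * bohr_radius()^2`), the package default in [pressure_model()].
#' @return Critical pressure, Pa.
#' @export
critical_pressure <- function(omega_x, m_eff, temperature, sigma) {
  stopifnot(is.numeric(omega_x), is.numeric(m_eff), is.numeric(temperature),
            is.numeric(sigma))
  if (any(omega_x < 0)) stop("omega_x must be non-negative")
  if (any(m_eff <= 0) || any(temperature <= 0)) stop("mass and temperature must be positive")
  if (any(sigma <= 0)) stop("cross-section sigma must be positive")
  omega_x * sqrt(2 * m_eff * .kB * temperature) / sigma
}

#' Bohr radius
#'
#' @return The Bohr radius in metres, for building cross-section estimates.
#' @export
bohr_radius <- function() .bohr_radius

#' Pressure-shifted tunneling frequency
#'
#' \eqn{\omega_x' = \omega_x\sqrt{1 - P/P_{cr}}}: the tunneling frequency is
#' suppressed with pressure and vanishes at the critical pressure.  Beyond
#' \eqn{P_{cr}} the tunneling is fully frozen; the function returns 0 there
#' with attribute `saturated = TRUE`.
#'
#' @param omega_x Zero-pressure tunneling frequency, Hz.
#' @param pressure Ambient pressure, Pa (non-negative).
#' @param p_cr Critical pressure, Pa (positive).
#' @return Shifted frequency \eqn{\omega_x'} in Hz, with logical attribute
#'   `saturated`.
#' @export
pressure_shifted_tunneling <- function(omega_x, pressure, p_cr) {
  stopifnot(is.numeric(omega_x), is.numeric(pressure), is.numeric(p_cr))
  if (any(pressure < 0)) stop("pressure must be non-negative")
  if (any(p_cr <= 0)) stop("critical pressure must be positive")
  saturated <- pressure >= p_cr
  out <- ifelse(saturated, 0, omega_x * sqrt(1 - pressure / p_cr))
  attr(out, "saturated") <- saturated
  out
}

#' Pressure model of an odorant
#'
#' Combines the mass and cross-section inputs of the collisional decoherence
#' picture into one object: effective mass, critical pressure and the
#' pressure-shifted tunneling frequency at the given ambient pressure.
#'
#' @param omega_x Zero-pressure tunneling frequency, Hz.
#' @param mu Reduced mass of the odorant, kg.
#' @param m_t Average environment-collision mass, kg.
#' @param sigma Decoherence cross-section, m^2 (default 150 Bohr-radii
#'   squared; the hard-sphere room-temperature estimate).
#' @param temperature Temperature, K (default 300, room temperature).
#' @param pressure Ambient pressure, Pa; use [atm_to_pa()] for atmospheres.
#' @return Object of class `pressure_model` with fields `m_eff`,
#'   `critical_pressure` (Pa) and `omega_x_prime` (Hz).
#' @export
pressure_model <- function(omega_x, mu, m_t, sigma = 150 * .bohr_radius^2,
                           temperature = 300, pressure = 0) {
  m_eff <- effective_mass(mu, m_t)
  p_cr <- critical_pressure(omega_x, m_eff, temperature, sigma)
  wxp <- pressure_shifted_tunneling(omega_x, pressure, p_cr)
  structure(list(omega_x = omega_x, mu = mu, m_t = m_t, sigma = sigma,
                 temperature = temperature, pressure = pressure,
                 m_eff = m_eff, critical_pressure = p_cr,
                 omega_x_prime = as.numeric(wxp),
                 saturated = isTRUE(any(attr(wxp, "saturated")))),
            class = "pressure_model")
}

#' @export
print.pressure_model <- function(x, ...) {
  cat("Collisional pressure model\n")
  cat(sprintf("  omega_x (P=0)    : %.6g Hz\n", x$omega_x))
  cat(sprintf("  effective mass   : %.6g kg\n", x$m_eff))
  cat(sprintf("  critical pressure: %.6g Pa (%.4g atm)\n",
              x$critical_pressure, x$critical_pressure / .atm_pa))
  cat(sprintf("  omega_x'(P=%.4g atm): %.6g Hz%s\n", x$pressure / .atm_pa,
              x$omega_x_prime, if (x$saturated) "  [saturated]" else ""))
  invisible(x)
}

#' Atmosphere/pascal conversion
#'
#' @param atm,pa Pressure in atmospheres / pascals.
#' @return Converted pressure (101325 Pa per atm).
#' @export
atm_to_pa <- function(atm) atm * .atm_pa

#' @rdname atm_to_pa
#' @export
pa_to_atm <- function(pa) pa / .atm_pa

#' Isotope substitution scenario
#'
#' Rescales the odorant's reduced mass by `mass_scale` (isotope substitution
#' leaves the electronic potential unchanged, so to leading order only the
#' mass moves) and recomputes the effective mass, critical pressure and the
#' shifted tunneling frequency at the same ambient pressure.  For any fixed
#' \eqn{0 < P < P_{cr}}, a heavier isotope (`mass_scale > 1`) raises
#' \eqn{P_{cr}} and therefore raises \eqn{\omega_x'}: isotope substitution
#' sharpens pressure sensitivity.
#'
#' @param base A [pressure_model()].
#' @param mass_scale Positive multiplicative factor on the reduced mass.
#' @return A new `pressure_model`.
#' @export
isotope_scenario <- function(base, mass_scale) {
  stopifnot(inherits(base, "pressure_model"), is.finite(mass_scale))
  if (mass_scale <= 0) stop("mass_scale must be positive")
  pressure_model(omega_x = base$omega_x, mu = base$mu * mass_scale,
                 m_t = base$m_t, sigma = base$sigma,
                 temperature = base$temperature, pressure = base$pressure)
}

#' Chiral discrimination of enantiomer channels
#'
#' Computes the inelastic rates through the \eqn{|L\rangle\to|E_2\rangle} and
#' \eqn{|R\rangle\to|E_2\rangle} channels at identical parameters and their
#' ratio.  Because the two channels weight the polaron-frame Gaussians with
#' different trigonometric factors, the two enantiomeric preparations of the
#' same odorant transfer electrons at different rates; their ratio is the
#' model's chiral discrimination observable.
#'
#' @inheritParams closed_form_rate
#' @return Object of class `chiral_pair` with fields `rate_L`, `rate_R`
#'   (1/s) and `discrimination` (\eqn{\Gamma_L/\Gamma_R}).
#' @export
chiral_discrimination <- function(req, second_exponent = c("squared", "linear")) {
  stopifnot(inherits(req, "rate_request"))
  second_exponent <- match.arg(second_exponent)
  gl <- inelastic_rate_L_to_E2(req, second_exponent)
  gr <- inelastic_rate_R_to_E2(req, second_exponent)
  if (!is.finite(gr$gamma) || gr$gamma == 0)
    stop("R-channel rate vanished; discrimination ratio diverges")
  structure(list(odorant = req$odorant, rate_L = gl$gamma, rate_R = gr$gamma,
                 discrimination = gl$gamma / gr$gamma,
                 validity_flags = union(gl$validity_flags, gr$validity_flags)),
            class = "chiral_pair")
}

#' @export
print.chiral_pair <- function(x, ...) {
  cat("Chiral discrimination\n")
  cat(sprintf("  Gamma(L->E2)  : %.6g 1/s\n", x$rate_L))
  cat(sprintf("  Gamma(R->E2)  : %.6g 1/s\n", x$rate_R))
  cat(sprintf("  discrimination: %.6g\n", x$discrimination))
  if (length(x$validity_flags))
    cat("  flags         :", paste(x$validity_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Ammonia inversion fixture (synthetic masses)
#'
#' Named demonstration scenario for the pressure phenomenology: the ammonia
#' inversion mode with its low-pressure tunneling frequency
#' \eqn{\omega_x \approx 2.4\times10^{10}} Hz.  The masses entering the
#' critical-pressure formula are not fixed by the rate model itself; this
#' fixture uses synthetic estimates (inversion-mode reduced mass
#' \eqn{\mu \approx 4.1\times10^{-27}} kg, air-like collision mass
#' \eqn{m_t \approx 4.81\times10^{-26}} kg) with the default hard-sphere
#' cross-section, which lands \eqn{P_{cr}} at a few atmospheres — the right
#' order of magnitude, but not a quantitative reference value.  Use it for
#' qualitative exploration only.
#'
#' @param pressure Ambient pressure, Pa (default 1 atm).
#' @return A [pressure_model()].
#' @export
ammonia_fixture <- function(pressure = .atm_pa) {
  pressure_model(omega_x = 2.4e10, mu = 4.1e-27, m_t = 4.81e-26,
                 temperature = 300, pressure = pressure)
}
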