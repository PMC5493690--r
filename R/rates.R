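#' Rate request
#'
#' Bundles everything a rate evaluation needs: the odorant two-level system,
#' the electronic parameters (defaulting to the odorant-consistent values of
#' [default_electronic_parameters()]), the bath spectrum (defaulting to the
#' aqueous exponential-cutoff Ohmic bath), the thermal state and the requested
#' transition.
#'
#' @param odorant An [odorant_two_level()].
#' @param params An [electronic_parameters()]; default ties
#'   \eqn{\varepsilon,\Delta,\gamma} to the odorant.
#' @param spectrum A [bath_spectrum()]; default \eqn{J_0=1,\lambda=10^{12}} Hz.
#' @param state A [thermal_state()]; default biological temperature 310 K.
#' @param transition One of [transition_labels()].
#' @return Object of class `rate_request`.
#' @export
rate_request <- function(odorant,
                         params = default_electronic_parameters(odorant),
                         spectrum = bath_spectrum(),
                         state = thermal_state(310),
                         transition = "elastic") {
  stopifnot(inherits(odorant, "odorant_two_level"),
            inherits(params, "electronic_parameters"),
            inherits(spectrum, "bath_spectrum"),
            inherits(state, "thermal_state"))
  transition <- .check_transition(transition)
  structure(list(odorant = odorant, params = params, spectrum = spectrum,
                 state = state, transition = transition),
            class = "rate_request")
}

.rate_result <- function(gamma, transition, method, flags = character()) {
  structure(list(gamma = gamma, inverse = 1 / gamma, method = method,
                 transition = transition, validity_flags = flags),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("ET rate [%s, %s]\n", x$transition, x$method))
  cat(sprintf("  Gamma   : %.6g 1/s\n  1/Gamma : %.6g s\n", x$gamma, x$inverse))
  if (length(x$validity_flags))
    cat("  flags   :", paste(x$validity_flags, collapse = ", "), "\n")
  invisible(x)
}

# Kernel decomposition of a transition: each row is one oscillating term
# coef * exp(-1i * shift * tau) of <j|Omega(tau)|i><i|Omega(0)|j>, so that the
# high-temperature (Gaussian) evaluation of the rate integral turns the row
# into coef * sqrt(pi/a) * exp(-(eps - Er + shift)^2 / (4a)).  `eta_sum`
# marks the terms whose shift is +/-(eta_A + eta_D); these are the terms whose
# printed exponent differs between the two chiral-channel formula variants.
.kernel_terms <- function(transition, odorant, params,
                          frame = polaron_frame(odorant, params)) {
  th <- odorant$theta
  up <- frame$upsilon
  d  <- frame$eta_D - frame$eta_A   # eta_2 - eta_1
  s  <- frame$eta_A + frame$eta_D   # eta_1 + eta_2
  switch(transition,
    elastic = data.frame(coef = 1, shift = 0, eta_sum = FALSE),
    L_to_E2 = data.frame(
      coef = cos(th + up) * c(cos(th) * cos(up), -sin(th) * sin(up)),
      shift = c(d, -s),
      eta_sum = c(FALSE, TRUE)),
    R_to_E2 = data.frame(
      coef = sin(th + up) * c(sin(th) * cos(up), cos(th) * sin(up)),
      shift = c(-d, s),
      eta_sum = c(FALSE, TRUE)),
    E1_to_E2 = data.frame(
      coef = c(sin(up)^2 * cos(th)^2, sin(up)^2 * sin(th)^2,
               0.25 * sin(th) * sin(up), -0.25 * sin(th) * sin(up)),
      shift = c(-s, s, -d, d),
      eta_sum = FALSE),
    R_to_L = data.frame(coef = sin(up)^2, shift = s, eta_sum = FALSE),
    stop("unknown transition: ", transition))
}

.rate_flags <- function(req, gamma = NULL) {
  flags <- character()
  if (!weak_coupling_ok(req$params, req$spectrum))
    flags <- c(flags, "weak_coupling_violated")
  # high-temperature closed forms assume k_B T/h at or above the gap scale
  if (req$params$eps > req$state$thermal_frequency)
    flags <- c(flags, "high_temperature_questionable")
  if (!is.null(gamma) && is.finite(gamma) && gamma < 0)
    flags <- c(flags, "negative_rate")
  flags
}

#' Closed-form high-temperature electron transfer rate
#'
#' Marcus-type Gaussian rates obtained from the second-order transfer
#' probability in the polaron frame, in the high-temperature limit.  The
#' elastic channel is
#' \deqn{\Gamma = \Delta^2\sqrt{\frac{\pi}{k_BT\,E_r}}\,
#'   \exp\left\{-\frac{(\varepsilon-E_r)^2}{4k_BT\,E_r}\right\}}
#' with \eqn{E_r} the bath reorganization energy (equal to \eqn{J_0\lambda}
#' for the default bath) and \eqn{k_BT} expressed in Hz; the inelastic
#' channels carry additional trigonometric weights in \eqn{\theta},
#' \eqn{\upsilon} and shifted Gaussians in the polaron energies (see the
#' per-transition wrappers).
#'
#' Negative closed-form values (possible for the chiral channels when the
#' bracket of Gaussian terms changes sign) are reported with a
#' `"negative_rate"` validity flag, never clamped.
#'
#' @param req A [rate_request()].
#' @param second_exponent For the `L_to_E2` and `R_to_E2` channels only:
#'   `"squared"` (default) evaluates the \eqn{(\eta_A+\eta_D)}-shifted term
#'   with the usual Gaussian exponent, consistent with the kernel integral
#'   that [numeric_rate()] evaluates; `"linear"` evaluates that one exponent
#'   linearly, \eqn{\exp\{-(\varepsilon-E_r\mp(\eta_A+\eta_D))/(4k_BT E_r)\}},
#'   which is the variant that reproduces the published tunneling-dominant
#'   reference rates.  See the package vignette for why both exist.
#' @return A `rate_result` with fields `gamma` (1/s), `inverse` (s),
#'   `method`, `transition` and `validity_flags`.
#' @export
closed_form_rate <- function(req, second_exponent = c("squared", "linear")) {
  stopifnot(inherits(req, "rate_request"))
  second_exponent <- match.arg(second_exponent)
  er <- reorganization_energy(req$spectrum)
  if (er == 0) stop("vanishing reorganization energy: the high-temperature ",
                    "Gaussian rate is undefined for an uncoupled bath")
  kt <- req$state$thermal_frequency
  a <- kt * er
  terms <- .kernel_terms(req$transition, req$odorant, req$params)
  x <- req$params$eps - er + terms$shift
  expo <- ifelse(terms$eta_sum & second_exponent == "linear",
                 -x / (4 * a), -x^2 / (4 * a))
  gamma <- req$params$delta^2 * sqrt(pi / a) * sum(terms$coef * exp(expo))
  .rate_result(gamma, req$transition, "closed_form", .rate_flags(req, gamma))
}

#' @rdname transition_rates
#' @export
elastic_rate <- function(req) {
  req$transition <- "elastic"
  closed_form_rate(req)
}

#' Per-transition closed-form rates
#'
#' Convenience wrappers around [closed_form_rate()] for the odorant
#' transitions: the chiral channels \eqn{|L\rangle\to|E_2\rangle} and
#' \eqn{|R\rangle\to|E_2\rangle} (whose difference underlies enantiomer
#' discrimination), the eigenstate channel \eqn{|E_1\rangle\to|E_2\rangle},
#' the high-pressure handed flip \eqn{|R\rangle\to|L\rangle}, and the elastic
#' background channel.
#'
#' @inheritParams closed_form_rate
#' @return A `rate_result`.
#' @name transition_rates
NULL

#' @rdname transition_rates
#' @export
inelastic_rate_L_to_E2 <- function(req, second_exponent = c("squared", "linear")) {
  req$transition <- "L_to_E2"
  closed_form_rate(req, second_exponent)
}

#' @rdname transition_rates
#' @export
inelastic_rate_R_to_E2 <- function(req, second_exponent = c("squared", "linear")) {
  req$transition <- "R_to_E2"
  closed_form_rate(req, second_exponent)
}

#' @rdname transition_rates
#' @export
inelastic_rate_E1_to_E2 <- function(req) {
  req$transition <- "E1_to_E2"
  closed_form_rate(req)
}

#' @rdname transition_rates
#' @export
inelastic_rate_R_to_L <- function(req) {
  req$transition <- "R_to_L"
  closed_form_rate(req)
}

#' Inelastic-to-elastic rate ratio
#'
#' \eqn{\Gamma_{\mathrm{inelastic}}/\Gamma_{\mathrm{elastic}}} at identical
#' parameters; the quantity plotted throughout the odorant, temperature and
#' pressure analyses.  Ratios above 1 mark the regime where the vibrationally
#' assisted channel dominates the background.
#'
#' @inheritParams closed_form_rate
#' @return Dimensionless ratio.
#' @export
inelastic_to_elastic_ratio <- function(req, second_exponent = c("squared", "linear")) {
  stopifnot(inherits(req, "rate_request"))
  if (req$transition == "elastic")
    stop("request an inelastic transition to form the ratio")
  el <- elastic_rate(req)
  if (!is.finite(el$gamma) || el$gamma == 0)
    stop("elastic rate vanished; inelastic-to-elastic ratio diverges")
  closed_form_rate(req, second_exponent)$gamma / el$gamma
}

#' Numerical rate oracle
#'
#' Evaluates the transfer rate directly from the Markov-limit kernel integral
#' \deqn{\Gamma = \Delta^2\, 2\,\mathrm{Re}\int_0^{\tau_{\max}}
#'   e^{-i\varepsilon\tau}\, K_{ij}(\tau)\, f(\tau)\, d\tau,}
#' where \eqn{K_{ij}(\tau) = \langle j|\Omega(\tau)|i\rangle\langle
#' i|\Omega(0)|j\rangle} is the propagator kernel of the requested transition
#' (a sum of oscillating terms in the polaron shifts) and \eqn{f(\tau)} is the
#' bath correlation function.  The closed-form Gaussian rates are the
#' stationary high-temperature evaluation of this same integral, so agreement
#' between the two routes validates both.
#'
#' @param req A [rate_request()].
#' @param tau_max Upper limit of the time integral, s.  Default `NULL`
#'   starts from \eqn{8/\sqrt{k_BT\,E_r}} (eight widths of the Gaussian decay
#'   of the high-temperature correlation function) and doubles until the
#'   running integral is converged to `tol`.
#' @param tol Relative convergence tolerance of the `tau_max` extension
#'   (default `1e-6`).
#' @param correlation `"quadrature"` (default) uses [bath_correlation()];
#'   `"gaussian"` substitutes the analytic high-temperature approximation
#'   \eqn{f(\tau) = \exp(-k_BT\,E_r\,\tau^2 + iE_r\tau)}, for which the time
#'   integral reproduces the closed form essentially exactly (used as a
#'   self-test of the integrator).
#' @param n_tau Number of Simpson nodes per `tau_max` trial (odd; default 1601).
#' @return A `rate_result` with `method = "numeric"`.
#' @export
numeric_rate <- function(req, tau_max = NULL, tol = 1e-6,
                         correlation = c("quadrature", "gaussian"),
                         n_tau = 1601L) {
  stopifnot(inherits(req, "rate_request"))
  correlation <- match.arg(correlation)
  if (req$params$delta == 0)
    return(.rate_result(0, req$transition, "numeric", .rate_flags(req)))
  er <- reorganization_energy(req$spectrum)
  kt <- req$state$thermal_frequency
  a <- kt * er
  terms <- .kernel_terms(req$transition, req$odorant, req$params)
  f_of <- function(tau) {
    if (correlation == "gaussian") exp(-a * tau^2 + 1i * er * tau)
    else bath_correlation(tau, req$spectrum, req$state)
  }
  base <- if (is.null(tau_max)) 8 / sqrt(a) else tau_max
  eval_at <- function(tmax) {
    # keep node density fixed as the window extends
    n <- as.integer(ceiling(n_tau * tmax / base))
    if (n %% 2L == 0L) n <- n + 1L
    tau <- seq(0, tmax, length.out = n)
    f <- f_of(tau)
    h <- tau[2L] - tau[1L]
    w <- rep(c(2, 4), length.out = n); w[1L] <- 1; w[n] <- 1
    w <- w * h / 3
    g <- 0
    for (k in seq_len(nrow(terms))) {
      ph <- exp(-1i * (req$params$eps + terms$shift[k]) * tau)
      g <- g + terms$coef[k] * 2 * Re(sum(w * ph * f))
    }
    req$params$delta^2 * g
  }
  gamma <- eval_at(base)
  if (is.null(tau_max)) {
    scale <- c(1.5, 3, 6, 12)
    for (j in seq_along(scale)) {
      gamma2 <- eval_at(base * scale[j])
      ok <- abs(gamma2 - gamma) <= tol * max(abs(gamma2), 1e-300)
      gamma <- gamma2
      if (ok) break
      if (j == length(scale))
        stop("numeric rate did not converge within the tau_max ",
             "extension budget; last value ", gamma2)
    }
  }
  .rate_result(gamma, req$transition, "numeric", .rate_flags(req, gamma))
}
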