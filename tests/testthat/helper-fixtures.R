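# Shared fixtures: the aqueous bath, biological temperature, and a literal
# transcription of the closed-form rate expressions used as an independent
# oracle against the kernel-decomposition implementation.

aqueous <- function() bath_spectrum("ohmic_exponential", 1, 1e12)
body_temp <- function() thermal_state(310)

default_req <- function(omega_x, omega_z, transition = "elastic",
                        temperature = 310) {
  rate_request(odorant_two_level(omega_x, omega_z, warn = FALSE),
               spectrum = aqueous(),
               state = thermal_state(temperature),
               transition = transition)
}

# Independent literal evaluation of the five closed-form rate expressions,
# written term by term from the Gaussian formulas (not via the kernel-terms
# decomposition used by the package).
literal_rate <- function(req, transition = req$transition,
                         second_exponent = "squared") {
  od <- req$odorant
  pr <- req$params
  th <- 0.5 * atan2(od$omega_x, od$omega_z)
  up <- 0.5 * (atan((od$omega_x + pr$gamma_A) / od$omega_z) +
               atan((od$omega_x - pr$gamma_D) / od$omega_z))
  eD <- -(od$omega_z / 2) * cos(atan((od$omega_x - pr$gamma_D) / od$omega_z))
  eA <- -(od$omega_z / 2) * cos(atan((od$omega_x + pr$gamma_A) / od$omega_z))
  er <- req$spectrum$coupling * req$spectrum$cutoff
  kt <- req$state$thermal_frequency
  a4 <- 4 * kt * er
  pref <- pr$delta^2 * sqrt(pi / (kt * er))
  e2 <- function(x) exp(-x^2 / a4)        # Gaussian exponent
  e1 <- function(x) exp(-x / a4)          # linear-variant exponent
  esum <- if (second_exponent == "linear") e1 else e2
  x0 <- pr$eps - er
  switch(transition,
    elastic = pref * e2(x0),
    L_to_E2 = pref * cos(th + up) *
      (cos(th) * cos(up) * e2(x0 + (eD - eA)) -
       sin(th) * sin(up) * esum(x0 - (eA + eD))),
    R_to_E2 = pref * sin(th + up) *
      (sin(th) * cos(up) * e2(x0 - (eD - eA)) +
       cos(th) * sin(up) * esum(x0 + (eA + eD))),
    E1_to_E2 = pref *
      (sin(up)^2 * (cos(th)^2 * e2(x0 - (eA + eD)) +
                    sin(th)^2 * e2(x0 + (eA + eD))) +
       0.25 * sin(th) * sin(up) * (e2(x0 - (eD - eA)) - e2(x0 + (eD - eA)))),
    R_to_L = pref * sin(up)^2 * e2(x0 + (eA + eD)))
}
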