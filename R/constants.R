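# Physical constants (SI, CODATA 2018 exact values)
.kB <- 1.380649e-23          # Boltzmann constant, J/K
.planck_h <- 6.62607015e-34  # Planck constant, J s
.bohr_radius <- 5.29177210903e-11  # m
.atm_pa <- 101325            # Pa per standard atmosphere

# All model energies are ordinary frequencies in Hz (hbar = 1 convention of the
# rate formulas); the thermal energy enters as k_B*T/h.  See thermal_state().

# Closed set of odorant transitions accompanying an electron transfer event.
.transitions <- c("L_to_E2", "R_to_E2", "E1_to_E2", "R_to_L", "elastic")

# Mapping of the generic polaron shifts (eta_1, eta_2) appearing in the
# propagator phases and in the high-pressure R->L rate onto the named
# donor/acceptor shifts: eta_1 = eta_A, eta_2 = eta_D.  Centralised here so the
# phase eta_2 - eta_1 = eta_D - eta_A used by the rate kernels and the matrix
# propagator stays consistent.
.eta1 <- function(frame) frame$eta_A
.eta2 <- function(frame) frame$eta_D

# Paper-stated physical maximum for either odorant frequency (Hz); larger
# values are admitted but flagged.
.omega_physical_max <- 1e12

#' Transition labels
#'
#' The closed set of odorant transitions that can accompany an electron
#' transfer event: the three inelastic transitions out of a handed or energy
#' eigenstate (`"L_to_E2"`, `"R_to_E2"`, `"E1_to_E2"`), the high-pressure
#' handed-state flip (`"R_to_L"`), and the background `"elastic"` channel in
#' which the odorant is left untouched.
#'
#' @return Character vector of the five recognised transition labels.
#' @export
transition_labels <- function() .transitions

.check_transition <- function(transition) {
  transition <- match.arg(transition, .transitions)
  transition
}
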