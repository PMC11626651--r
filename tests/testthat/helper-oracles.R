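# Independent oracles the implementation is checked against.

# Electron count from explicitly balancing the oxidation half-reaction
#   CaHbOc + w H2O -> a CO2 + h H+ + e e-
# by solving the O/H/charge balance as a linear system (independent of the
# degree-of-reduction shortcut used in the package).
oracle_half_reaction_electrons <- function(C, H, O) {
  # unknowns: w (water), h (protons), e (electrons)
  # O:  O + w = 2 C
  # H:  H + 2 w = h
  # charge: h - e = 0
  A <- rbind(
    c(1, 0, 0),
    c(2, -1, 0),
    c(0, 1, -1)
  )
  b <- c(2 * C - O, -H, 0)
  sol <- solve(A, b)
  sol[3]
}

# Ideal-gas amount via SI units (Pa, m^3 -> mol -> mmol), an independent
# unit path from the kPa/mL arithmetic in the package.
oracle_ideal_gas_mmol <- function(p_kPa, v_mL, T_K) {
  (p_kPa * 1e3) * (v_mL * 1e-6) / (8.314 * T_K) * 1e3
}

zero_noise <- c(pressure = 0, fractions = 0, concentrations = 0)

# small hand-built event-free trajectory
make_simple_gas <- function(times = c(0, 16),
                            pressures = c(210, 190),
                            x_CO = c(0.2, 0.1)) {
  n <- length(times)
  tibble::tibble(
    time_d = times,
    pressure_kPa = pressures,
    x_CO = x_CO,
    x_CO2 = 0.25,
    x_H2 = 0.05,
    x_CH4 = 0,
    x_N2 = 1 - x_CO - 0.25 - 0.05
  )
}
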