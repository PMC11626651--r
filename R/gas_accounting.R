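#' Total headspace gas amount from the ideal gas law
#'
#' `n = p V / (R T)`; with pressure in kPa, volume in mL and temperature in
#' K the result is directly in mmol (8.314 kPa mL / (mmol K)).
#'
#' @param pressure_kPa absolute headspace pressure, kPa.
#' @param headspace_mL headspace volume, mL (> 0).
#' @param temp_K temperature, K.
#' @return total gas amount, mmol.
#' @examples
#' headspace_moles(210, 200, 298.15) # ~16.94 mmol
#' @export
headspace_moles <- function(pressure_kPa, headspace_mL, temp_K) {
  if (any(headspace_mL <= 0)) abort("headspace volume must be > 0")
  if (any(temp_K <= 0)) abort("temperature must be > 0 K")
  if (any(pressure_kPa < 0)) abort("pressure must be >= 0")
  pressure_kPa * headspace_mL / (.R_GAS * temp_K)
}

#' Per-species headspace amounts
#'
#' Splits the total ideal-gas amount of a headspace state across the five
#' measured gases by mole fraction; the species amounts close exactly on
#' the total.
#'
#' @param state one-row tibble (or list) with `pressure_kPa`, `temp_K` and
#'   the mole-fraction columns `x_CO`, `x_CO2`, `x_H2`, `x_CH4`, `x_N2`.
#' @param headspace_mL headspace volume, mL.
#' @return named numeric vector of mmol per gas (`CO`, `CO2`, `H2`, `CH4`,
#'   `N2`).
#' @export
species_moles <- function(state, headspace_mL) {
  total <- headspace_moles(state$pressure_kPa, headspace_mL, state$temp_K)
  x <- unlist(state[.GAS_COLS], use.names = FALSE)
  setNames(total * x, sub("^x_", "", .GAS_COLS))
}

# species mmol for every state of a validated trajectory -> matrix
.state_species_matrix <- function(states) {
  total <- headspace_moles(states$pressure_kPa, states$headspace_mL,
                           states$temp_K)
  m <- as.matrix(states[.GAS_COLS]) * total
  colnames(m) <- sub("^x_", "", .GAS_COLS)
  m
}

#' Cumulative per-gas consumption/production over a bottle trajectory
#'
#' Net biological gas turnover by interval differencing of ideal-gas
#' inventories: for each pair of consecutive states the per-species change
#' `n(end) - n(start)` is accumulated, except across
#' flush-and-repressurise events, where the post-flush state restarts the
#' baseline (the exchanged gas is not biology). Gas withdrawn by sampling
#' is valued at the state measured at the sample time (pressure,
#' temperature and composition of that state) and added back, since removed
#' moles are neither consumption nor production; a sample taken between a
#' measurement and the flush that follows it is absorbed by the excluded
#' flush interval. Production is positive, consumption negative.
#'
#' @param trajectory a `ferm_trajectory` from [validate_trajectory()], or
#'   the arguments to build one.
#' @inheritParams validate_trajectory
#' @return tibble with columns `compound` (CO, CO2, H2, CH4, N2) and
#'   `n_mmol` (net produced, negative = consumed).
#' @export
cumulative_balance <- function(trajectory, events = NULL,
                               spec = bottle_spec()) {
  if (!inherits(trajectory, "ferm_trajectory")) {
    trajectory <- validate_trajectory(trajectory, events, spec)
  }
  states <- trajectory$states
  ev <- trajectory$events
  nmat <- .state_species_matrix(states)
  k <- nrow(states)
  gases <- colnames(nmat)

  # anchor each gas sample to the state it was drawn from: the last state at
  # time <= event time, preferring the measured (pre-flush) state on ties
  samples <- ev[ev$kind == "gas_sample", , drop = FALSE]
  correction <- matrix(0, nrow = k, ncol = length(gases),
                       dimnames = list(NULL, gases))
  if (nrow(samples)) {
    for (i in seq_len(nrow(samples))) {
      t_ev <- samples$time_d[i]
      cand <- which(states$time_d <= t_ev)
      if (!length(cand)) next
      at_t <- cand[states$time_d[cand] == t_ev & states$event[cand] == "measure"]
      anchor <- if (length(at_t)) at_t[length(at_t)] else cand[length(cand)]
      frac_removed <- samples$volume_mL[i] / states$headspace_mL[anchor]
      correction[anchor, ] <- correction[anchor, ] + nmat[anchor, ] * frac_removed
    }
  }

  net <- setNames(numeric(length(gases)), gases)
  for (j in seq_len(k - 1)) {
    if (states$event[j + 1] == "post_flush") next # baseline reset
    net <- net + (nmat[j + 1, ] - nmat[j, ]) + correction[j, ]
  }
  tibble(compound = gases, n_mmol = unname(net))
}
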