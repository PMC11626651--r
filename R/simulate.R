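.SIM_GASES <- c("CO", "CO2", "H2", "CH4", "N2")
.SIM_LIQUIDS <- c("formate", "acetate", "ethanol", "propionate",
                  "n_butyrate", "n_valerate")

#' Stoichiometric scenario reaction
#'
#' A conversion with a signed stoichiometry over registry compounds (checked
#' for elemental balance) and a rate constant in mmol reaction extent per
#' litre of initial broth per day. `inhibited` marks whether the
#' undissociated-acid inhibition factor of the scenario applies to this
#' reaction.
#'
#' @param name reaction name.
#' @param stoichiometry named signed coefficients (products positive).
#' @param k rate constant, mmol/L/d (`>= 0`).
#' @param inhibited apply the scenario's HAc inhibition factor?
#' @param registry compound registry.
#' @return a `sim_reaction` list.
#' @export
sim_reaction <- function(name, stoichiometry, k, inhibited = TRUE,
                         registry = default_registry()) {
  if (k < 0) abort("rate constant must be >= 0")
  rxn <- reaction(name, stoichiometry, registry = registry) # element check
  structure(
    list(name = name, stoichiometry = rxn$stoichiometry, k = k,
         inhibited = inhibited),
    class = "sim_reaction"
  )
}

#' @rdname scenario_reactions
#' @export
rxn_hydrogenogenesis <- function(k = 4, ...) {
  sim_reaction("carboxydotrophic hydrogenogenesis",
               c(CO = -1, H2O = -1, H2 = 1, CO2 = 1), k, ...)
}

#' @rdname scenario_reactions
#' @export
rxn_carboxydotrophic_acetogenesis <- function(k = 2, ...) {
  sim_reaction("carboxydotrophic acetogenesis",
               c(CO = -4, H2O = -2, acetate = 1, CO2 = 2), k, ...)
}

#' @rdname scenario_reactions
#' @export
rxn_hydrogenotrophic_methanogenesis <- function(k = 1.5, ...) {
  sim_reaction("hydrogenotrophic methanogenesis",
               c(H2 = -4, CO2 = -1, CH4 = 1, H2O = 2), k, ...)
}

#' @rdname scenario_reactions
#' @export
rxn_acetoclastic_methanogenesis <- function(k = 1.5, ...) {
  sim_reaction("acetoclastic methanogenesis",
               c(acetate = -1, CH4 = 1, CO2 = 1), k, ...)
}

#' @rdname scenario_reactions
#' @export
rxn_sao <- function(k = 1, ...) {
  sim_reaction("syntrophic acetate oxidation",
               c(acetate = -1, H2O = -2, H2 = 4, CO2 = 2), k, ...)
}

#' @rdname scenario_reactions
#' @export
rxn_chain_elongation_butyrate <- function(k = 0.5, ...) {
  sim_reaction("chain elongation to n-butyrate",
               c(acetate = -2, H2 = -2, n_butyrate = 1, H2O = 2), k, ...)
}

#' Scenario reaction builders
#'
#' Element-balanced conversions of the mixed-culture syngas/acetate
#' repertoire: the biological water-gas shift, acetogenesis from CO or H2,
#' methanogenesis from H2/CO2 or acetate, syntrophic acetate oxidation, and
#' reverse-beta-oxidation chain elongation to n-butyrate and n-valerate. All
#' conserve electron equivalents, so simulated ground truths are
#' electron-conserving by construction.
#'
#' @param k rate constant, mmol reaction extent per litre initial broth per
#'   day.
#' @param ... passed to [sim_reaction()] (e.g. `inhibited = FALSE`).
#' @return a `sim_reaction`.
#' @name scenario_reactions
#' @export
rxn_chain_elongation_valerate <- function(k = 0.5, ...) {
  sim_reaction("chain elongation to n-valerate",
               c(propionate = -1, acetate = -1, H2 = -2, n_valerate = 1,
                 H2O = 2), k, ...)
}

#' Fermentation scenario
#'
#' Bundles the active conversions with the (synthetic-only) inhibition
#' kinetics, lag phase and observation noise. Inhibition multiplies every
#' `inhibited` reaction's rate by `1 / (1 + (HAc / K_I)^hill)` where HAc is
#' the current undissociated acetic acid concentration from the bottle's pH
#' and temperature; the default `K_I = 0.77` gHAc/L with `hill = 2` places
#' ~90% inhibition at 2.3 gHAc/L. Noise is multiplicative on observations
#' only — the simulated state (and hence the ground truth) stays exact.
#'
#' @param reactions list of [sim_reaction()]s.
#' @param K_I half-inhibition constant, gHAc/L.
#' @param hill Hill exponent of the inhibition term.
#' @param lag_d lag phase, d (rates are zero before it).
#' @param noise named relative standard deviations for `pressure`,
#'   `fractions` and `concentrations` observations.
#' @param seed RNG seed for reproducible observation noise.
#' @param Ka optional acetic-acid dissociation constant override (else
#'   looked up from the bottle temperature).
#' @return a `ferm_scenario` list.
#' @examples
#' scenario_methanogenic(seed = 1)
#' @export
ferm_scenario <- function(reactions, K_I = 0.77, hill = 2, lag_d = 1,
                          noise = c(pressure = 0.01, fractions = 0.01,
                                    concentrations = 0.01),
                          seed = NULL, Ka = NULL) {
  if (K_I <= 0) abort("K_I must be > 0")
  if (any(noise < 0)) abort("noise sds must be >= 0")
  for (nm in c("pressure", "fractions", "concentrations")) {
    if (!nm %in% names(noise)) noise[[nm]] <- 0
  }
  structure(
    list(reactions = reactions, K_I = K_I, hill = hill, lag_d = lag_d,
         noise = noise, seed = seed, Ka = Ka),
    class = "ferm_scenario"
  )
}

#' @rdname ferm_scenario
#' @param ... overrides passed to [ferm_scenario()].
#' @export
scenario_methanogenic <- function(...) {
  ferm_scenario(
    reactions = list(
      rxn_hydrogenogenesis(k = 4),
      rxn_hydrogenotrophic_methanogenesis(k = 1.5),
      rxn_acetoclastic_methanogenesis(k = 1.5)
    ),
    ...
  )
}

#' @rdname ferm_scenario
#' @export
scenario_chain_elongation <- function(...) {
  ferm_scenario(
    reactions = list(
      rxn_hydrogenogenesis(k = 8, inhibited = FALSE),
      rxn_chain_elongation_butyrate(k = 0.5, inhibited = FALSE)
    ),
    ...
  )
}

#' @rdname ferm_scenario
#' @export
scenario_abiotic <- function(...) {
  ferm_scenario(reactions = list(), ...)
}

#' Simulate one batch bottle
#'
#' Event-driven simulation of a sealed serum bottle over the fermentation
#' horizon, emulating the measurement protocol: daily headspace measurement
#' followed by a 3 mL gas sample; flush-and-repressurise to 210 kPa with
#' 3:20:25 kPa-proportion H2:CO:CO2 in N2 whenever the measured pressure is
#' below 180 kPa or the CO fraction below 1%; a 1 mL broth sample every
#' 2 days (taken after the day's gas handling, so it affects the headspace
#' volume of later states only). Reaction extents advance by fixed-step
#' explicit integration (default 0.05 d) with positivity guards (an extent
#' is capped at the limiting species' inventory), are scaled by the HAc
#' inhibition factor, and are accumulated exactly into the ground truth.
#' Extents are expressed per litre of initial broth, so the ground-truth
#' liquid mmol coincide with the concentration-change convention the
#' analysis uses.
#'
#' @param spec a [bottle_spec()].
#' @param scenario a [ferm_scenario()].
#' @param horizon_d fermentation length, d.
#' @param dt integration step, d.
#' @param gas_sample_mL daily gas sample volume.
#' @param liquid_sample_mL broth sample volume.
#' @param liquid_sample_every_d broth sampling interval, d.
#' @param flush_below_kPa flush trigger pressure.
#' @param flush_below_xco flush trigger CO fraction.
#' @param refill_kPa re-pressurisation target, kPa.
#' @param refill_kPa_parts named partial-pressure proportions of H2, CO and
#'   CO2 in the refill gas (N2 is the remainder), scaled to `refill_kPa`.
#' @return a `bottle_sim` list with tibbles `gas`, `events`, `liquid`, the
#'   `truth` ledger (exact net mmol, rates, yields) and the inputs.
#' @export
simulate_bottle <- function(spec, scenario = scenario_methanogenic(),
                            horizon_d = 16, dt = 0.05,
                            gas_sample_mL = 3, liquid_sample_mL = 1,
                            liquid_sample_every_d = 2,
                            flush_below_kPa = 180, flush_below_xco = 0.01,
                            refill_kPa = 210,
                            refill_kPa_parts = c(H2 = 3, CO = 20, CO2 = 25)) {
  run <- function() {
    .simulate_bottle_impl(spec, scenario, horizon_d, dt, gas_sample_mL,
                          liquid_sample_mL, liquid_sample_every_d,
                          flush_below_kPa, flush_below_xco, refill_kPa,
                          refill_kPa_parts)
  }
  if (!is.null(scenario$seed)) withr::with_seed(scenario$seed, run()) else run()
}

.simulate_bottle_impl <- function(spec, scenario, horizon_d, dt,
                                  gas_sample_mL, liquid_sample_mL,
                                  liquid_sample_every_d, flush_below_kPa,
                                  flush_below_xco, refill_kPa,
                                  refill_kPa_parts) {
  registry <- default_registry()
  temp_K <- spec$temp_K
  v_start_L <- spec$liquid_volume_mL / 1000
  m_acetate <- registry_row(registry, "acetate")$molar_mass
  Ka <- if (!is.null(scenario$Ka)) scenario$Ka else acetate_ka(spec$temp_C)
  f_hac <- undissociated_fraction(spec$pH, Ka)

  refill_frac <- c(refill_kPa_parts,
                   N2 = refill_kPa - sum(refill_kPa_parts)) / refill_kPa
  refill_frac <- refill_frac[.SIM_GASES]
  refill_frac[is.na(refill_frac)] <- 0
  names(refill_frac) <- .SIM_GASES

  v_liq <- spec$liquid_volume_mL
  v_head <- spec$bottle_volume_mL - v_liq
  gas <- refill_frac * headspace_moles(refill_kPa, v_head, temp_K) # mmol
  liq <- setNames(numeric(length(.SIM_LIQUIDS)), .SIM_LIQUIDS)     # mM
  liq["acetate"] <- spec$acetate_gL / m_acetate * 1000
  truth <- setNames(numeric(length(c(.SIM_GASES, .SIM_LIQUIDS))),
                    c(.SIM_GASES, .SIM_LIQUIDS))

  noise <- scenario$noise
  obs_mult <- function(n, sd) {
    if (sd <= 0) rep(1, n) else pmax(1 + rnorm(n, 0, sd), 0)
  }

  gas_rows <- list()
  event_rows <- list()
  liquid_rows <- list()

  record_gas <- function(time, event) {
    p_true <- sum(gas) * .R_GAS * temp_K / v_head
    x_true <- gas / sum(gas)
    p_obs <- p_true * obs_mult(1, noise[["pressure"]])
    x_obs <- x_true * obs_mult(length(x_true), noise[["fractions"]])
    x_obs <- x_obs / sum(x_obs)
    gas_rows[[length(gas_rows) + 1]] <<- tibble(
      time_d = time, event = event, pressure_kPa = p_obs, temp_K = temp_K,
      x_CO = x_obs[["CO"]], x_CO2 = x_obs[["CO2"]], x_H2 = x_obs[["H2"]],
      x_CH4 = x_obs[["CH4"]], x_N2 = x_obs[["N2"]]
    )
    list(p_true = p_true, x_true = x_true)
  }
  record_event <- function(time, kind, volume) {
    event_rows[[length(event_rows) + 1]] <<- tibble(
      time_d = time, kind = kind, volume_mL = volume
    )
  }

  step_reactions <- function() {
    acetate_gL_now <- liq[["acetate"]] * m_acetate / 1000
    hac <- acetate_gL_now * f_hac
    inhib <- 1 / (1 + (hac / scenario$K_I)^scenario$hill)
    for (r in scenario$reactions) {
      rate <- r$k * (if (r$inhibited) inhib else 1)
      if (rate <= 0) next
      extent <- rate * v_start_L * dt # mmol of reaction
      consumed <- r$stoichiometry[r$stoichiometry < 0]
      for (cmp in names(consumed)) {
        if (cmp == "H2O") next
        avail <- if (cmp %in% .SIM_GASES) gas[[cmp]] else {
          liq[[cmp]] * v_start_L
        }
        extent <- min(extent, avail / abs(consumed[[cmp]]))
      }
      if (extent <= 0) next
      for (cmp in names(r$stoichiometry)) {
        if (cmp == "H2O") next
        d <- r$stoichiometry[[cmp]] * extent
        if (cmp %in% .SIM_GASES) {
          gas[cmp] <<- max(gas[[cmp]] + d, 0)
        } else {
          liq[cmp] <<- max(liq[[cmp]] + d / v_start_L, 0)
        }
        truth[cmp] <<- truth[[cmp]] + d
      }
    }
  }

  n_flushes <- 0L
  for (day in 0:horizon_d) {
    if (day > 0) {
      n_sub <- max(1L, round(1 / dt))
      for (s in seq_len(n_sub)) {
        if ((day - 1) + s * dt > scenario$lag_d) step_reactions()
      }
    }
    st <- record_gas(day, "measure")
    # daily gas sample, drawn at headspace pressure/composition
    gas <- gas * (1 - gas_sample_mL / v_head)
    record_event(day, "gas_sample", gas_sample_mL)
    # flush decision on the measured state
    if (st$p_true < flush_below_kPa || st$x_true[["CO"]] < flush_below_xco) {
      gas <- refill_frac * headspace_moles(refill_kPa, v_head, temp_K)
      record_event(day, "flush", v_head)
      record_gas(day, "post_flush")
      n_flushes <- n_flushes + 1L
    }
    # broth sample last, so it affects only later headspace volumes
    if (day %% liquid_sample_every_d == 0) {
      conc_gL <- vapply(.SIM_LIQUIDS, function(cmp) {
        liq[[cmp]] * registry_row(registry, cmp)$molar_mass / 1000
      }, numeric(1))
      conc_obs <- conc_gL * obs_mult(length(conc_gL),
                                     noise[["concentrations"]])
      liquid_rows[[length(liquid_rows) + 1]] <- as_tibble(
        c(list(time_d = day), as.list(conc_obs))
      )
      v_liq <- v_liq - liquid_sample_mL
      v_head <- spec$bottle_volume_mL - v_liq
      record_event(day, "liquid_sample", liquid_sample_mL)
    }
  }

  truth_flows <- tibble(compound = names(truth), n_mmol = unname(truth)) %>%
    assign_roles() %>%
    mutate(
      e_mmol = .data$n_mmol *
        vapply(.data$compound,
               function(cmp) registry_row(registry, cmp)$eeq, numeric(1),
               USE.NAMES = FALSE),
      q_emol = emol_rate(.data$n_mmol, .data$compound, spec, horizon_d,
                         registry),
      q_cmol = cmol_rate(.data$n_mmol, .data$compound, spec, horizon_d,
                         registry)
    )
  substrate_e <- abs(sum(truth_flows$e_mmol[truth_flows$role == "substrate"]))
  truth_yields <- if (substrate_e > 0) product_yields(truth_flows, registry)
    else list(yields = tibble(compound = character(), yield_pct = numeric()),
              electron_recovery_pct = NA_real_)

  structure(
    list(
      gas = bind_rows(gas_rows),
      events = bind_rows(event_rows),
      liquid = bind_rows(liquid_rows),
      truth = list(
        flows = truth_flows,
        yields = truth_yields$yields,
        electron_recovery_pct = truth_yields$electron_recovery_pct,
        n_flushes = n_flushes,
        t_total_d = horizon_d
      ),
      spec = spec,
      scenario = scenario
    ),
    class = "bottle_sim"
  )
}

#' @export
print.bottle_sim <- function(x, ...) {
  cat(sprintf(
    "<bottle_sim> %s (rep %s): %d gas states, %d events, %d flushes\n",
    x$spec$condition_label, x$spec$replicate_id, nrow(x$gas),
    nrow(x$events), x$truth$n_flushes
  ))
  invisible(x)
}

#' Full factorial bottle design
#'
#' Expands acetate levels x pH x temperature x replicates into one bottle
#' spec per row, with a distinct RNG seed per bottle and the zero-acetate
#' control present in every (pH, temperature) stratum when `0` is among the
#' levels. The defaults mirror the stated design: 14 acetate levels, pH 6.7
#' and 5.5, 37 and 55 degC, triplicates (168 bottles).
#'
#' @param acetate_gL acetate levels, g/L.
#' @param pH pH levels.
#' @param temp_C temperatures, degC.
#' @param replicates replicate count per condition.
#' @param base_seed integer; bottle seeds are `base_seed + row index`.
#' @return tibble with the design columns, `condition_label`, `seed` and a
#'   `spec` list-column of [bottle_spec()]s.
#' @export
make_experiment_grid <- function(acetate_gL = c(0, 1, 2, 4, 6, 8, 12, 16,
                                                24, 32, 40, 48, 56, 64),
                                 pH = c(6.7, 5.5), temp_C = c(37, 55),
                                 replicates = 3, base_seed = 1) {
  if (!length(acetate_gL)) abort("acetate_gL must be non-empty")
  grid <- tidyr::expand_grid(
    acetate_gL = acetate_gL, pH = pH, temp_C = temp_C,
    replicate_id = seq_len(replicates)
  ) %>%
    mutate(seed = base_seed + dplyr::row_number())
  grid %>%
    mutate(spec = purrr::pmap(
      list(.data$acetate_gL, .data$pH, .data$temp_C, .data$replicate_id),
      function(a, p, tc, r) {
        bottle_spec(acetate_gL = a, pH = p, temp_C = tc, replicate_id = r)
      }
    )) %>%
    mutate(condition_label = purrr::map_chr(.data$spec, "condition_label"))
}

#' Simulate every bottle of a design grid
#'
#' @param grid a [make_experiment_grid()] tibble.
#' @param scenario_factory function of `(spec, seed)` returning the
#'   [ferm_scenario()] for one bottle; defaults to [scenario_methanogenic()]
#'   seeded per bottle.
#' @param ... passed to [simulate_bottle()].
#' @return list of `bottle_sim` objects, directly consumable by
#'   [analyze_experiment()].
#' @export
simulate_experiment <- function(grid, scenario_factory = NULL, ...) {
  if (is.null(scenario_factory)) {
    scenario_factory <- function(spec, seed) scenario_methanogenic(seed = seed)
  }
  purrr::pmap(
    list(grid$spec, grid$seed),
    function(spec, seed) {
      simulate_bottle(spec, scenario_factory(spec, seed), ...)
    }
  )
}
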