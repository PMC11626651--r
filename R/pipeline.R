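#' Balance a single bottle
#'
#' End-to-end balancing of one serum bottle: validates the headspace
#' trajectory, accumulates per-gas turnover across flush and sampling events
#' ([cumulative_balance()]), converts the first-to-last liquid concentration
#' changes to mmol ([liquid_net_mmol()]), assigns substrate/product roles,
#' and computes electron-mole and carbon-mole space-time rates, electron
#' yields and the electron recovery.
#'
#' @param gas headspace states table (see [validate_trajectory()]).
#' @param events event log table.
#' @param liquid tibble of broth samples: `time_d` plus one g/L column per
#'   measured metabolite (registry names). Only the first and last rows
#'   enter the balance; intermediate samples are for plotting.
#' @param spec a [bottle_spec()].
#' @param t_total_d total fermentation time, d; defaults to the trajectory
#'   span.
#' @param registry compound registry.
#' @return a `ferm_balance` object; see [tidy.ferm_balance()] and
#'   [glance.ferm_balance()].
#' @export
analyze_bottle <- function(gas, events = NULL, liquid = NULL,
                           spec = bottle_spec(), t_total_d = NULL,
                           registry = default_registry()) {
  traj <- if (inherits(gas, "ferm_trajectory")) gas else {
    validate_trajectory(gas, events, spec)
  }
  if (is.null(t_total_d)) {
    t_total_d <- diff(range(traj$states$time_d))
  }
  flows <- cumulative_balance(traj)

  if (!is.null(liquid) && nrow(liquid) >= 1) {
    liquid <- arrange(as_tibble(liquid), .data$time_d)
    cmps <- intersect(names(liquid), registry$compound)
    if (length(cmps)) {
      first <- unlist(liquid[1, cmps])
      last <- unlist(liquid[nrow(liquid), cmps])
      flows <- bind_rows(flows, liquid_net_mmol(first, last, spec, registry))
    }
  }

  flows <- flows %>%
    assign_roles() %>%
    mutate(
      eeq = vapply(.data$compound,
                   function(cmp) registry_row(registry, cmp)$eeq, numeric(1),
                   USE.NAMES = FALSE),
      carbon = vapply(.data$compound,
                      function(cmp) registry_row(registry, cmp)$carbon,
                      numeric(1), USE.NAMES = FALSE),
      e_mmol = .data$n_mmol * .data$eeq,
      q_emol = emol_rate(.data$n_mmol, .data$compound, spec, t_total_d,
                         registry),
      q_cmol = cmol_rate(.data$n_mmol, .data$compound, spec, t_total_d,
                         registry)
    )

  substrate_e <- abs(sum(flows$e_mmol[flows$role == "substrate"]))
  py <- if (substrate_e > 0) product_yields(flows, registry) else {
    list(yields = tibble(compound = character(), yield_pct = numeric()),
         electron_recovery_pct = NA_real_)
  }
  structure(
    list(
      flows = flows,
      yields = py$yields,
      electron_recovery_pct = py$electron_recovery_pct,
      spec = traj$spec,
      t_total_d = t_total_d,
      n_flushes = sum(traj$events$kind == "flush")
    ),
    class = "ferm_balance"
  )
}

#' @export
print.ferm_balance <- function(x, ...) {
  cat(sprintf(
    "<ferm_balance> %s (rep %s): %g d, %d flushes, electron recovery %.1f%%\n",
    x$spec$condition_label, x$spec$replicate_id, x$t_total_d, x$n_flushes,
    x$electron_recovery_pct
  ))
  print(x$flows)
  invisible(x)
}

#' Tidy a bottle balance
#'
#' One row per compound: net mmol (production positive), substrate/product
#' role, cumulative e-mmol, e-mM/d and C-mM/d rates, and the electron yield
#' for products.
#'
#' @param x a `ferm_balance`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.ferm_balance <- function(x, ...) {
  x$flows %>%
    left_join(x$yields, by = "compound") %>%
    mutate(
      condition_label = x$spec$condition_label,
      replicate_id = x$spec$replicate_id
    ) %>%
    select("condition_label", "replicate_id", "compound", "role", "n_mmol",
           "e_mmol", "q_emol", "q_cmol", "yield_pct")
}

#' One-row summary of a bottle balance
#'
#' @param x a `ferm_balance`.
#' @param ... unused.
#' @return a tibble with the condition, fermentation time, flush count,
#'   substrate electron consumption and electron recovery.
#' @export
glance.ferm_balance <- function(x, ...) {
  substrate_e <- x$flows %>%
    filter(.data$role == "substrate") %>%
    pull("e_mmol") %>%
    sum() %>%
    abs()
  tibble(
    condition_label = x$spec$condition_label,
    replicate_id = x$spec$replicate_id,
    acetate_gL = x$spec$acetate_gL,
    pH = x$spec$pH,
    temp_C = x$spec$temp_C,
    t_total_d = x$t_total_d,
    n_flushes = x$n_flushes,
    substrate_e_mmol = substrate_e,
    electron_recovery_pct = x$electron_recovery_pct
  )
}

#' Balance a set of bottles
#'
#' Applies [analyze_bottle()] to each bottle of an experiment (e.g. the
#' output of [simulate_experiment()] or a bundle read with
#' [read_experiment()]) and collects tidy per-bottle flows plus per-bottle
#' summaries.
#'
#' @param bottles list of bottles, each a list with elements `gas`,
#'   `events`, `liquid` and `spec`.
#' @param ... passed on to [analyze_bottle()].
#' @return a `ferm_experiment` object: list with `flows` (long tibble of all
#'   per-bottle compound flows), `bottles` (per-bottle glance rows) and
#'   `results` (list of `ferm_balance` objects).
#' @export
analyze_experiment <- function(bottles, ...) {
  results <- purrr::map(bottles, function(b) {
    analyze_bottle(b$gas, b$events, b$liquid, b$spec, ...)
  })
  structure(
    list(
      flows = purrr::map_dfr(results, tidy),
      bottles = purrr::map_dfr(results, glance),
      results = results
    ),
    class = "ferm_experiment"
  )
}

#' @export
print.ferm_experiment <- function(x, ...) {
  cat(sprintf(
    "<ferm_experiment> %d bottles, %d conditions\n",
    nrow(x$bottles), dplyr::n_distinct(x$bottles$condition_label)
  ))
  print(x$bottles)
  invisible(x)
}

#' Per-condition replicate summary of an experiment
#'
#' Mean and sample standard deviation across replicates of the per-compound
#' net mmol, cumulative e-mmol, e-mM/d and C-mM/d.
#'
#' @param experiment a `ferm_experiment`.
#' @return tibble keyed by `condition_label` and `compound` with
#'   `*_mean`/`*_sd` columns and the replicate count.
#' @export
summarize_experiment <- function(experiment) {
  meta <- experiment$bottles %>%
    distinct(.data$condition_label, .data$acetate_gL, .data$pH, .data$temp_C)
  experiment$flows %>%
    group_by(.data$condition_label, .data$compound, .data$role) %>%
    summarise(
      across(c("n_mmol", "e_mmol", "q_emol", "q_cmol"),
             list(mean = mean,
                  sd = ~ if (dplyr::n() >= 2) stats::sd(.x) else NA_real_)),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) %>%
    left_join(meta, by = "condition_label")
}

#' Control-normalised cumulative electron turnover
#'
#' For every (pH, temperature) stratum, normalises each condition's
#' replicate-mean cumulative e-mmol per compound to the stratum's control
#' (the condition with `control_acetate_gL` supplemented acetate, default
#' 0 g/L), via [normalize_to_control()]. Sign changes between condition and
#' control mark a switch between net production and net consumption.
#'
#' @param experiment a `ferm_experiment`.
#' @param compounds compounds to normalise (default CO, H2, CH4, acetate).
#' @param control_acetate_gL acetate load identifying the control condition.
#' @return tibble with stratum, condition, compound, condition/control
#'   e-mmol and the signed ratio.
#' @export
normalize_experiment <- function(experiment,
                                 compounds = c("CO", "H2", "CH4", "acetate"),
                                 control_acetate_gL = 0) {
  means <- experiment$flows %>%
    left_join(
      distinct(experiment$bottles, .data$condition_label, .data$acetate_gL,
               .data$pH, .data$temp_C),
      by = "condition_label"
    ) %>%
    filter(.data$compound %in% compounds) %>%
    group_by(.data$pH, .data$temp_C, .data$acetate_gL,
             .data$condition_label, .data$compound) %>%
    summarise(e_mmol = mean(.data$e_mmol), .groups = "drop")

  strata <- distinct(means, .data$pH, .data$temp_C)
  purrr::pmap_dfr(strata, function(pH, temp_C) {
    stratum <- filter(means, .data$pH == .env$pH, .data$temp_C == .env$temp_C)
    control <- filter(stratum, .data$acetate_gL == control_acetate_gL)
    if (!nrow(control)) {
      warn(sprintf("no control (%g g/L) condition at pH %g / %g degC",
                   control_acetate_gL, pH, temp_C))
      return(tibble())
    }
    purrr::map_dfr(
      unique(stratum$condition_label),
      function(lbl) {
        cond <- filter(stratum, .data$condition_label == lbl)
        normalize_to_control(cond, control) %>%
          mutate(condition_label = lbl, pH = .env$pH, temp_C = .env$temp_C,
                 acetate_gL = cond$acetate_gL[1], .before = 1)
      }
    )
  })
}
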