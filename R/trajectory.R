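#' Bottle specification
#'
#' Geometry and initial conditions of one serum bottle: the stated world is
#' a 250 mL bottle with 50 mL of broth, incubated at 37 or 55 degC, pH
#' adjusted to 6.7 or 5.5, with an initial acetate load between 0 and
#' 64 g/L.
#'
#' @param bottle_volume_mL total bottle volume, mL.
#' @param liquid_volume_mL initial broth volume (V_Start), mL; must be
#'   positive and smaller than the bottle volume.
#' @param temp_C incubation temperature, degC.
#' @param pH initial adjusted pH (held fixed for speciation).
#' @param acetate_gL initial total acetate load, g/L.
#' @param na_eq_gL measured sodium-equivalent metadata, g/L (optional,
#'   carried through only).
#' @param condition_label free-text condition label.
#' @param replicate_id replicate identifier.
#' @return a `bottle_spec` list.
#' @examples
#' bottle_spec(acetate_gL = 12, pH = 5.5, temp_C = 55)
#' @export
bottle_spec <- function(bottle_volume_mL = 250, liquid_volume_mL = 50,
                        temp_C = 37, pH = 6.7, acetate_gL = 0,
                        na_eq_gL = NA_real_, condition_label = NULL,
                        replicate_id = 1L) {
  if (liquid_volume_mL <= 0 || liquid_volume_mL >= bottle_volume_mL) {
    abort("need 0 < liquid_volume_mL < bottle_volume_mL")
  }
  if (temp_C <= -273.15) abort("temperature below absolute zero")
  if (pH <= 0 || pH >= 14) abort("pH must be in (0, 14)")
  if (acetate_gL < 0) abort("acetate_gL must be >= 0")
  if (is.null(condition_label)) {
    condition_label <- sprintf("%gg/L_pH%g_%gC", acetate_gL, pH, temp_C)
  }
  structure(
    list(
      bottle_volume_mL = bottle_volume_mL,
      liquid_volume_mL = liquid_volume_mL,
      temp_C = temp_C,
      temp_K = temp_C + 273.15,
      pH = pH,
      acetate_gL = acetate_gL,
      na_eq_gL = na_eq_gL,
      condition_label = condition_label,
      replicate_id = replicate_id
    ),
    class = "bottle_spec"
  )
}

#' @export
print.bottle_spec <- function(x, ...) {
  cat(sprintf(
    "<bottle_spec> %s (rep %s): %g mL bottle, %g mL broth, %g degC, pH %g, %g g/L acetate\n",
    x$condition_label, x$replicate_id, x$bottle_volume_mL,
    x$liquid_volume_mL, x$temp_C, x$pH, x$acetate_gL
  ))
  invisible(x)
}

#' Validate and prepare a headspace trajectory
#'
#' Checks a gas-phase time series and its event log against the bottle
#' specification, renormalises the measured mole fractions (micro-GC
#' percentages do not close exactly; deviations of the fraction sum from 1
#' up to `fraction_tol` are absorbed by renormalisation, larger ones are an
#' error) and attaches the headspace volume at every state. The headspace
#' volume at a state at time t is
#' `bottle volume - (initial broth volume - liquid withdrawn before t)`:
#' liquid samples taken at a measurement time take effect for later states.
#'
#' @param gas tibble with columns `time_d`, `pressure_kPa`, the mole-fraction
#'   columns `x_CO`, `x_CO2`, `x_H2`, `x_CH4`, `x_N2`, and optionally
#'   `event` (`"measure"`, default, or `"post_flush"`) and `temp_K`
#'   (defaulting to the bottle's incubation temperature).
#' @param events tibble with columns `time_d`, `kind` (`"gas_sample"`,
#'   `"liquid_sample"` or `"flush"`) and `volume_mL`; may be `NULL` or empty.
#'   Every `flush` event must have a matching `post_flush` gas state at the
#'   same time.
#' @param spec a [bottle_spec()].
#' @param fraction_tol tolerance on `|sum(fractions) - 1|` before
#'   renormalisation (default 0.02).
#' @return a `ferm_trajectory` list with elements `spec`, `states` (gas
#'   tibble with renormalised fractions and `headspace_mL`) and `events`.
#' @export
validate_trajectory <- function(gas, events = NULL, spec = bottle_spec(),
                                fraction_tol = 0.02) {
  gas <- as_tibble(gas)
  need <- c("time_d", "pressure_kPa", .GAS_COLS)
  missing_cols <- setdiff(need, names(gas))
  if (length(missing_cols)) {
    abort(paste0("gas table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(gas) < 2) abort("need at least two headspace states")
  if (!"event" %in% names(gas)) gas$event <- "measure"
  if (!"temp_K" %in% names(gas)) gas$temp_K <- spec$temp_K
  gas$temp_K[is.na(gas$temp_K)] <- spec$temp_K
  if (any(!gas$event %in% c("measure", "post_flush"))) {
    abort("gas 'event' must be 'measure' or 'post_flush'")
  }
  if (any(!is.finite(gas$pressure_kPa)) || any(gas$pressure_kPa < 0)) {
    abort("pressures must be finite and >= 0")
  }
  if (any(gas$temp_K <= 0)) abort("temperatures must be > 0 K")

  # measure sorts before post_flush at the same timestamp
  gas <- gas %>%
    mutate(.ord = ifelse(.data$event == "post_flush", 1L, 0L)) %>%
    arrange(.data$time_d, .data$.ord) %>%
    select(-".ord")
  dup <- gas %>%
    dplyr::count(.data$time_d, .data$event) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicated gas state at time(s) ",
                 paste(dup$time_d, collapse = ", ")))
  }

  frac <- as.matrix(gas[.GAS_COLS])
  if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1)) {
    abort("mole fractions must be finite and in [0, 1]")
  }
  s <- rowSums(frac)
  off <- abs(s - 1) > fraction_tol
  if (any(off)) {
    abort(paste0(
      "mole-fraction sums outside 1 +/- ", fraction_tol, " at time(s) ",
      paste(gas$time_d[off], collapse = ", ")
    ))
  }
  gas[.GAS_COLS] <- frac / s

  if (is.null(events)) {
    events <- tibble(time_d = numeric(), kind = character(),
                     volume_mL = numeric())
  }
  events <- as_tibble(events)
  if (nrow(events)) {
    ev_need <- c("time_d", "kind", "volume_mL")
    if (length(setdiff(ev_need, names(events)))) {
      abort("events table needs columns time_d, kind, volume_mL")
    }
    if (any(!events$kind %in% .EVENT_KINDS)) {
      abort(paste0("event kind must be one of: ",
                   paste(.EVENT_KINDS, collapse = ", ")))
    }
    events <- arrange(events, .data$time_d,
                      match(.data$kind, .EVENT_KINDS))
    span <- range(gas$time_d)
    if (any(events$time_d < span[1] | events$time_d > span[2])) {
      abort("event times must lie within the state time span")
    }
    flushes <- filter(events, .data$kind == "flush")
    post <- filter(gas, .data$event == "post_flush")
    if (!all(flushes$time_d %in% post$time_d)) {
      abort("every flush event needs a post_flush gas state at the same time")
    }
    if (!all(post$time_d %in% flushes$time_d)) {
      abort("post_flush gas state without a flush event")
    }
  } else if (any(gas$event == "post_flush")) {
    abort("post_flush gas state without a flush event")
  }

  liq <- filter(events, .data$kind == "liquid_sample")
  removed_before <- vapply(
    gas$time_d,
    function(t) sum(liq$volume_mL[liq$time_d < t]),
    numeric(1)
  )
  liquid_now <- spec$liquid_volume_mL - removed_before
  if (any(liquid_now <= 0)) {
    abort("liquid sampling drives broth volume to <= 0")
  }
  gas$headspace_mL <- spec$bottle_volume_mL - liquid_now

  structure(
    list(spec = spec, states = gas, events = events),
    class = "ferm_trajectory"
  )
}

#' @export
print.ferm_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ferm_trajectory> %s: %d states over %g-%g d, %d events (%d flushes)\n",
    x$spec$condition_label, nrow(x$states), min(x$states$time_d),
    max(x$states$time_d), nrow(x$events),
    sum(x$events$kind == "flush")
  ))
  invisible(x)
}
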