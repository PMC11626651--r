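#' Acetic-acid dissociation constant at the incubation temperatures
#'
#' The design grid uses two incubation temperatures with fixed dissociation
#' constants: Ka = 1.70e-5 mol/L at 37 degC and Ka = 1.58e-5 mol/L at 55 degC.
#' Other temperatures are not interpolated; supply `Ka` explicitly to the
#' speciation functions if you need one.
#'
#' @param temp_C incubation temperature in degrees Celsius (37 or 55).
#' @return Ka in mol/L.
#' @examples
#' acetate_ka(37)
#' @export
acetate_ka <- function(temp_C) {
  ka <- c(`37` = 1.70e-5, `55` = 1.58e-5)
  key <- as.character(temp_C)
  if (any(!key %in% names(ka))) {
    abort(paste0(
      "no registered Ka at ", paste(setdiff(key, names(ka)), collapse = ", "),
      " degC; registered temperatures are 37 and 55. Pass Ka explicitly."
    ))
  }
  unname(ka[key])
}

#' Fraction of total acetate present as undissociated acetic acid
#'
#' Henderson-Hasselbalch speciation of a monoprotic acid:
#' `f = C_H+ / (Ka + C_H+)` with `C_H+ = 10^-pH`. Strictly decreasing in pH
#' and increasing in `Ka^-1`.
#'
#' @param pH broth pH (0 < pH < 14).
#' @param Ka dissociation constant, mol/L.
#' @return fraction in `[0, 1]`.
#' @examples
#' undissociated_fraction(pH = -log10(1.70e-5), Ka = 1.70e-5) # 0.5 at pKa
#' @export
undissociated_fraction <- function(pH, Ka) {
  if (any(!is.finite(pH)) || any(!is.finite(Ka))) {
    abort("pH and Ka must be finite")
  }
  if (any(Ka <= 0)) abort("Ka must be > 0")
  if (any(pH <= 0 | pH >= 14)) abort("pH must be in (0, 14)")
  h <- 10^(-pH)
  h / (Ka + h)
}

#' Undissociated acetic acid concentration
#'
#' Converts a total acetate concentration (dissociated + undissociated, g/L)
#' into the concentration of the undissociated, membrane-permeant form (HAc,
#' g/L): total is converted to mol/L with the molar mass, multiplied by the
#' undissociated fraction, and converted back with the same molar mass — so
#' the result is independent of the molar-mass constant (it cancels), which
#' the `molar_mass` argument exists to demonstrate.
#'
#' @param acetate_gL total acetate concentration, g/L (`>= 0`).
#' @param pH broth pH.
#' @param temp_C temperature in degC used to look up Ka (ignored when `Ka`
#'   is supplied).
#' @param Ka optional explicit dissociation constant, mol/L.
#' @param molar_mass molar mass used for the (cancelling) g/L <-> mol/L
#'   round trip; any positive value gives the same result.
#' @return HAc concentration in g/L.
#' @examples
#' hac_concentration(64, pH = 5.5, temp_C = 37) # 10.04 g/L
#' hac_concentration(40, pH = 6.7, temp_C = 37) # 0.46 g/L
#' @export
hac_concentration <- function(acetate_gL, pH, temp_C = NULL, Ka = NULL,
                              molar_mass = 60.052) {
  if (any(acetate_gL < 0)) abort("acetate_gL must be >= 0")
  if (any(molar_mass <= 0)) abort("molar_mass must be > 0")
  if (is.null(Ka)) {
    if (is.null(temp_C)) abort("supply either temp_C or Ka")
    Ka <- acetate_ka(temp_C)
  }
  mol <- acetate_gL / molar_mass
  mol * undissociated_fraction(pH, Ka) * molar_mass
}

#' Undissociated-acid grid over acetate levels, pH and temperature
#'
#' Reconstructs the experimental design table: one row per (acetate level,
#' pH, temperature) combination with the undissociated acetic acid
#' concentration. `digits` optionally adds a half-away-from-zero rounded
#' column for comparison against printed tables.
#'
#' @param acetate_gL acetate levels, g/L (non-empty).
#' @param pH pH levels.
#' @param temp_C temperatures, degC (must have registered Ka, see
#'   [acetate_ka()]).
#' @param digits optional decimal count for a `hac_rounded_gL` column.
#' @return tibble with columns `acetate_gL`, `pH`, `temp_C`, `hac_gL`
#'   (and `hac_rounded_gL` when `digits` is given).
#' @examples
#' speciation_grid(c(0, 12, 64), pH = c(6.7, 5.5), temp_C = c(37, 55))
#' @export
speciation_grid <- function(acetate_gL, pH = c(6.7, 5.5),
                            temp_C = c(37, 55), digits = NULL) {
  if (length(acetate_gL) == 0) abort("acetate_gL must be non-empty")
  grid <- tidyr::expand_grid(
    acetate_gL = acetate_gL, pH = pH, temp_C = temp_C
  ) %>%
    mutate(hac_gL = hac_concentration(.data$acetate_gL, .data$pH,
                                      temp_C = .data$temp_C))
  if (!is.null(digits)) {
    grid <- mutate(grid, hac_rounded_gL = round_half_away(.data$hac_gL, digits))
  }
  grid
}
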