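#' Compound registry for fermentation balancing
#'
#' Every balancing step (electron-mole rates, carbon-mole rates, liquid
#' mmol conversion) looks compounds up in a registry tibble holding the
#' elemental composition of the neutral species, its molar mass, its electron
#' equivalents (e-mol released per mol on complete oxidation to CO2 and H2O)
#' and its carbon number. Electron equivalents follow the degree-of-reduction
#' rule `eeq = 4 C + H - 2 O`, which is what balancing the oxidation
#' half-reaction of a C/H/O compound yields; CO2, N2 and H2O therefore carry
#' zero electrons. The dissociation state does not change eeq, so entries are
#' defined on the neutral (acid) species.
#'
#' @return A tibble with one row per compound and columns `compound`, `C`,
#'   `H`, `O`, `N` (atom counts), `molar_mass` (g/mol, computed from the
#'   formula), `eeq` (e-mol/mol), `carbon` (C atoms), `phase`
#'   (`"gas"` or `"liquid"`).
#' @examples
#' default_registry()
#' @export
default_registry <- function() {
  reg <- tibble::tribble(
    ~compound,     ~C, ~H, ~O, ~N, ~phase,
    "CO",           1,  0,  1,  0, "gas",
    "CO2",          1,  0,  2,  0, "gas",
    "H2",           0,  2,  0,  0, "gas",
    "CH4",          1,  4,  0,  0, "gas",
    "N2",           0,  0,  0,  2, "gas",
    "formate",      1,  2,  2,  0, "liquid",
    "acetate",      2,  4,  2,  0, "liquid",
    "ethanol",      2,  6,  1,  0, "liquid",
    "propionate",   3,  6,  2,  0, "liquid",
    "n_butyrate",   4,  8,  2,  0, "liquid",
    "n_valerate",   5, 10,  2,  0, "liquid",
    "H2O",          0,  2,  1,  0, "liquid"
  )
  reg %>%
    mutate(
      molar_mass = 12.011 * .data$C + 1.008 * .data$H +
        15.999 * .data$O + 14.007 * .data$N,
      eeq = electron_equivalents(.data$C, .data$H, .data$O),
      carbon = .data$C
    ) %>%
    select("compound", "C", "H", "O", "N",
           "molar_mass", "eeq", "carbon", "phase")
}

#' Electron equivalents from elemental composition
#'
#' Degree-of-reduction rule for a compound CcHhOo oxidised completely to CO2
#' and H2O: `eeq = 4 C + H - 2 O`. Nitrogen is not counted (no N compounds
#' with catabolic electron content appear in this system; N2 is inert).
#'
#' @param C,H,O atom counts of the neutral species (vectorised).
#' @return e-mol released per mol, always `>= 0` for valid compounds.
#' @examples
#' electron_equivalents(1, 0, 1) # CO -> 2
#' electron_equivalents(2, 4, 2) # acetic acid -> 8
#' @export
electron_equivalents <- function(C, H, O) {
  eeq <- 4 * C + H - 2 * O
  if (any(eeq < 0)) {
    abort("negative electron equivalents: formula is more oxidised than CO2/H2O")
  }
  eeq
}

#' Add or override a compound in a registry
#'
#' Electron equivalents are derived from the formula unless given explicitly
#' (e.g. for compounds whose oxidation reference differs from CO2/H2O).
#'
#' @param registry a registry tibble (see [default_registry()]).
#' @param compound compound name.
#' @param C,H,O,N atom counts of the neutral species.
#' @param phase `"gas"` or `"liquid"`.
#' @param eeq optional explicit electron equivalents; defaults to `4C + H - 2O`.
#' @param molar_mass optional explicit molar mass (g/mol).
#' @return the registry with the compound appended (replacing any same-named
#'   entry).
#' @examples
#' default_registry() |> register_compound("n_caproate", C = 6, H = 12, O = 2)
#' @export
register_compound <- function(registry, compound, C, H, O, N = 0,
                              phase = "liquid", eeq = NULL,
                              molar_mass = NULL) {
  if (is.null(eeq)) eeq <- electron_equivalents(C, H, O)
  if (is.null(molar_mass)) {
    molar_mass <- 12.011 * C + 1.008 * H + 15.999 * O + 14.007 * N
  }
  row <- tibble(
    compound = compound, C = C, H = H, O = O, N = N,
    molar_mass = molar_mass, eeq = eeq, carbon = C, phase = phase
  )
  bind_rows(filter(registry, .data$compound != .env$compound), row)
}

# internal: single-row lookup with a clear error
registry_row <- function(registry, compound) {
  row <- registry[registry$compound == compound, ]
  if (nrow(row) != 1L) {
    abort(paste0("compound '", compound, "' is not in the registry"))
  }
  row
}
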