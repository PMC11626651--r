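#' Define a catabolic reaction
#'
#' Signed stoichiometry (products positive, substrates negative) over
#' registry compounds plus the special species `"H+"` (one hydrogen, charge
#' +1, activity taken from pH). Elemental balance over C, H and O is checked
#' at construction; `dG0_prime` is the Gibbs free energy at the chosen
#' reference conditions and is a user input — no standard-formation database
#' is bundled.
#'
#' @param name reaction name.
#' @param stoichiometry named numeric vector of signed coefficients.
#' @param dG0_prime reference Gibbs free energy, kJ/mol reaction.
#' @param reference_T temperature of the reference state, K.
#' @param registry compound registry used for the element check.
#' @return a `ferm_reaction` list.
#' @examples
#' reaction("hydrogenogenesis",
#'          c(CO = -1, H2O = -1, H2 = 1, CO2 = 1), dG0_prime = -20)
#' @export
reaction <- function(name, stoichiometry, dG0_prime = NA_real_,
                     reference_T = 298.15, registry = default_registry()) {
  if (is.null(names(stoichiometry)) || any(names(stoichiometry) == "")) {
    abort("stoichiometry must be a named vector")
  }
  if (any(stoichiometry == 0)) abort("coefficients must be nonzero")
  balance <- c(C = 0, H = 0, O = 0)
  for (cmp in names(stoichiometry)) {
    counts <- if (cmp == "H+") {
      c(C = 0, H = 1, O = 0)
    } else {
      row <- registry_row(registry, cmp)
      c(C = row$C, H = row$H, O = row$O)
    }
    balance <- balance + stoichiometry[[cmp]] * counts
  }
  if (any(abs(balance) > 1e-9)) {
    abort(paste0("reaction '", name, "' is not element-balanced: ",
                 paste(names(balance), balance, sep = "=", collapse = ", ")))
  }
  structure(
    list(name = name, stoichiometry = stoichiometry,
         dG0_prime = dG0_prime, reference_T = reference_T),
    class = "ferm_reaction"
  )
}

#' @export
print.ferm_reaction <- function(x, ...) {
  s <- x$stoichiometry
  side <- function(sel) paste(
    ifelse(abs(s[sel]) == 1, names(s)[sel],
           paste0(abs(s[sel]), " ", names(s)[sel])),
    collapse = " + "
  )
  cat(sprintf("<reaction> %s: %s -> %s (dG0' = %g kJ/mol)\n", x$name,
              side(s < 0), side(s > 0), x$dG0_prime))
  invisible(x)
}

#' Mass-action reaction quotient
#'
#' `Q = prod(activity^coefficient)` over all participants, with water
#' activity fixed at 1 and the proton activity `10^-pH` unless supplied
#' explicitly. Dissolved species enter as mol/L, gases as bar (the
#' convention of the thermodynamic analyses this supports).
#'
#' @param rxn a [reaction()].
#' @param activities named numeric vector of activities for the non-water
#'   participants.
#' @param pH pH supplying the proton activity when `"H+"` participates.
#' @return the quotient Q.
#' @export
reaction_quotient <- function(rxn, activities = numeric(), pH = NULL) {
  q <- 1
  for (cmp in names(rxn$stoichiometry)) {
    if (cmp == "H2O") next
    a <- if (cmp %in% names(activities)) {
      activities[[cmp]]
    } else if (cmp == "H+" && !is.null(pH)) {
      10^(-pH)
    } else {
      abort(paste0("missing activity for '", cmp, "'"))
    }
    if (!is.finite(a) || a <= 0) {
      abort(paste0("activity of '", cmp, "' must be finite and > 0"))
    }
    q <- q * a^rxn$stoichiometry[[cmp]]
  }
  q
}

#' Gibbs free energy under non-standard conditions
#'
#' `dG = dG0' + R T ln Q` in kJ/mol. This is the only temperature dependence
#' modelled; `dG0_prime` itself is not corrected away from its reference
#' temperature.
#'
#' @inheritParams reaction_quotient
#' @param temp_K temperature, K.
#' @return Gibbs free energy, kJ/mol reaction.
#' @examples
#' rxn <- reaction("hydrogenogenesis",
#'                 c(CO = -1, H2O = -1, H2 = 1, CO2 = 1), dG0_prime = -20)
#' delta_g(rxn, c(CO = 0.2, H2 = 0.03, CO2 = 0.25), temp_K = 310)
#' @export
delta_g <- function(rxn, activities = numeric(), pH = NULL, temp_K = 298.15) {
  if (is.na(rxn$dG0_prime)) abort("reaction has no dG0_prime")
  q <- reaction_quotient(rxn, activities, pH)
  rxn$dG0_prime + .R_GAS * temp_K * log(q) / 1000
}

#' Example catabolic reactions
#'
#' The four CO/H2/acetate reactions whose favourability frames mixed-culture
#' syngas fermentation, with *approximate* literature-style reference
#' energies (kJ/mol at ~298 K, pH 7-style reference); they are examples for
#' exercising [delta_g()] across pH/acetate grids, not certified constants —
#' replace `dG0_prime` with values from your own reference set for real
#' analyses.
#'
#' @param registry compound registry.
#' @return named list of [reaction()]s.
#' @export
example_reactions <- function(registry = default_registry()) {
  list(
    carboxydotrophic_hydrogenogenesis = reaction(
      "carboxydotrophic hydrogenogenesis",
      c(CO = -1, H2O = -1, H2 = 1, CO2 = 1),
      dG0_prime = -20, registry = registry
    ),
    carboxydotrophic_acetogenesis = reaction(
      "carboxydotrophic acetogenesis",
      c(CO = -4, H2O = -2, acetate = 1, CO2 = 2),
      dG0_prime = -175, registry = registry
    ),
    hydrogenotrophic_acetogenesis = reaction(
      "hydrogenotrophic acetogenesis",
      c(H2 = -4, CO2 = -2, acetate = 1, H2O = 2),
      dG0_prime = -95, registry = registry
    ),
    syntrophic_acetate_oxidation = reaction(
      "syntrophic acetate oxidation",
      c(acetate = -1, H2O = -2, H2 = 4, CO2 = 2),
      dG0_prime = 95, registry = registry
    )
  )
}
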