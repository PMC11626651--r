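#' Net liquid metabolite turnover between first and last broth samples
#'
#' Converts the concentration change of each measured metabolite between the
#' initial and final broth sample into mmol using the initial broth volume:
#' `n = (c_last - c_first) / M * V_Start`. Concentrations are intensive, so
#' liquid withdrawals do not change them; using V_Start treats the withdrawn
#' broth as if it had stayed, matching the rate normalisation.
#'
#' @param first,last named numeric vectors (or one-row data frames) of
#'   concentrations in g/L, named by registry compound.
#' @param spec a [bottle_spec()] (provides V_Start).
#' @param registry compound registry, see [default_registry()].
#' @return tibble with `compound` and `n_mmol` (net produced; negative =
#'   consumed).
#' @examples
#' liquid_net_mmol(c(acetate = 12), c(acetate = 4), bottle_spec())
#' @export
liquid_net_mmol <- function(first, last, spec = bottle_spec(),
                            registry = default_registry()) {
  first <- unlist(first)
  last <- unlist(last)
  compounds <- union(names(first), names(last))
  if (!length(compounds)) abort("no named concentrations supplied")
  if (any(c(first, last) < 0, na.rm = TRUE)) {
    abort("concentrations must be >= 0")
  }
  v_start_L <- spec$liquid_volume_mL / 1000
  purrr::map_dfr(compounds, function(cmp) {
    row <- registry_row(registry, cmp)
    c0 <- if (cmp %in% names(first)) first[[cmp]] else 0
    c1 <- if (cmp %in% names(last)) last[[cmp]] else 0
    tibble(
      compound = cmp,
      n_mmol = (c1 - c0) / row$molar_mass * v_start_L * 1000
    )
  })
}

#' Electron-mole space-time rate
#'
#' `q = n * eeq / (V_Start * t)`: net mmol scaled by the compound's electron
#' equivalents, normalised to the initial broth volume (L) and the total
#' fermentation time (d). Sign follows the net amount (production positive).
#'
#' @param n_mmol net amount, mmol.
#' @param compound registry compound name (scalar or vector matching
#'   `n_mmol`).
#' @param spec a [bottle_spec()].
#' @param t_total_d total fermentation time, d (> 0).
#' @param registry compound registry.
#' @return rate in e-mM/d.
#' @examples
#' emol_rate(-10, "CO", bottle_spec(), 16) # -25 e-mM/d
#' @export
emol_rate <- function(n_mmol, compound, spec = bottle_spec(),
                      t_total_d = 16, registry = default_registry()) {
  .space_time_rate(n_mmol, compound, spec, t_total_d, registry, "eeq")
}

#' Carbon-mole space-time rate
#'
#' Same normalisation as [emol_rate()] with the carbon number in place of
#' electron equivalents; carbon-free compounds (H2) contribute zero.
#'
#' @inheritParams emol_rate
#' @return rate in C-mM/d.
#' @examples
#' cmol_rate(-10, "CO", bottle_spec(), 16) # -12.5 C-mM/d
#' @export
cmol_rate <- function(n_mmol, compound, spec = bottle_spec(),
                      t_total_d = 16, registry = default_registry()) {
  .space_time_rate(n_mmol, compound, spec, t_total_d, registry, "carbon")
}

.space_time_rate <- function(n_mmol, compound, spec, t_total_d, registry,
                             weight_col) {
  if (t_total_d <= 0) abort("t_total_d must be > 0")
  w <- vapply(compound, function(cmp) registry_row(registry, cmp)[[weight_col]],
              numeric(1))
  v_start_L <- spec$liquid_volume_mL / 1000
  unname(n_mmol * w / (v_start_L * t_total_d))
}

# compounds that switch between substrate and product depending on the sign
# of their net turnover; everything else consumed is a substrate, produced a
# product
.DUAL_ROLE <- c("H2", "acetate")
.ALWAYS_SUBSTRATE <- c("CO")

#' Assign substrate/product roles to net flows
#'
#' CO (and CO2, electron-free) count as substrates when consumed; H2 and
#' acetate are substrates only when net-consumed, otherwise products; all
#' other metabolites and CH4 are products.
#'
#' @param flows tibble with `compound` and `n_mmol`.
#' @return `flows` with a `role` column (`"substrate"` / `"product"`).
#' @export
assign_roles <- function(flows) {
  mutate(flows, role = ifelse(
    (.data$compound %in% c(.ALWAYS_SUBSTRATE, "CO2", .DUAL_ROLE)) &
      .data$n_mmol < 0,
    "substrate", "product"
  ))
}

#' Product yields and electron recovery
#'
#' Yields on an electron basis: each product's electrons as a percentage of
#' the electrons of the consumed substrates,
#' `yield_i = n_i eeq_i / (n_syngas,cons eeq_syngas + n_acetate,cons
#' eeq_acetate) * 100`. "Syngas consumed" is the summed electron consumption
#' of CO and H2 (each only when net-consumed; CO2 carries no electrons).
#' The electron recovery is the sum over products and can exceed 100% when
#' extra electron sources (e.g. inoculum solids) feed the system.
#'
#' @param flows tibble with `compound` and `n_mmol` (net produced, negative
#'   = consumed); roles are assigned by [assign_roles()] if no `role` column
#'   is present.
#' @param registry compound registry.
#' @return list with `yields` (tibble `compound`, `yield_pct` for products)
#'   and `electron_recovery_pct`.
#' @examples
#' product_yields(tibble::tibble(
#'   compound = c("CO", "CH4"), n_mmol = c(-10, 2.5)
#' ))
#' @export
product_yields <- function(flows, registry = default_registry()) {
  if (!"role" %in% names(flows)) flows <- assign_roles(flows)
  flows <- flows %>%
    mutate(eeq = vapply(.data$compound,
                        function(cmp) registry_row(registry, cmp)$eeq,
                        numeric(1), USE.NAMES = FALSE),
           e_mmol = .data$n_mmol * .data$eeq)
  denom <- flows %>%
    filter(.data$role == "substrate") %>%
    pull("e_mmol") %>%
    sum() %>%
    abs()
  if (denom <= 0) {
    abort("no substrate electrons consumed: yields undefined")
  }
  products <- flows %>%
    filter(.data$role == "product", .data$eeq > 0) %>%
    mutate(yield_pct = pmax(.data$e_mmol, 0) / denom * 100) %>%
    select("compound", "yield_pct")
  list(
    yields = products,
    electron_recovery_pct = sum(products$yield_pct)
  )
}

#' Normalise condition flows to a control
#'
#' Ratio of cumulative electron turnover in a condition to the control
#' (typically the 0 g/L-acetate bottles of the same pH/temperature stratum),
#' per compound: `ratio = condition / |control|`. The sign is preserved, so
#' a compound that is consumed in the condition but produced in the control
#' (or vice versa) gets a negative ratio — the signature of a metabolic
#' switch. Compounds with zero control turnover are flagged rather than
#' divided through.
#'
#' @param condition,control tibbles with `compound` and a value column
#'   (default `e_mmol`) of cumulative electron turnover (sign: production
#'   positive).
#' @param value name of the value column.
#' @return tibble with `compound`, condition/control values, `ratio` and
#'   `zero_control` flag (`ratio` is `NA` where flagged).
#' @export
normalize_to_control <- function(condition, control, value = "e_mmol") {
  cond <- condition %>% select("compound", cond_value = all_of(value))
  ctrl <- control %>% select("compound", ctrl_value = all_of(value))
  left_join(cond, ctrl, by = "compound") %>%
    mutate(
      zero_control = is.na(.data$ctrl_value) | .data$ctrl_value == 0,
      ratio = ifelse(.data$zero_control, NA_real_,
                     .data$cond_value / abs(.data$ctrl_value))
    )
}

#' Replicate mean and standard deviation
#'
#' Arithmetic mean and sample (n-1) standard deviation across replicate
#' bottles; a single replicate reports `NA` for the sd.
#'
#' @param x numeric vector of per-bottle values.
#' @return tibble with `mean`, `sd`, `n`.
#' @examples
#' aggregate_replicates(c(8.0, 8.1, 8.2))
#' @export
aggregate_replicates <- function(x) {
  tibble(
    mean = mean(x),
    sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
    n = length(x)
  )
}
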