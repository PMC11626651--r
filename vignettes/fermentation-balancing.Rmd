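---
title: "Balancing batch-bottle syngas and acetate co-fermentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balancing batch-bottle syngas and acetate co-fermentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermbalance)
```

`fermbalance` quantifies what a mixed anaerobic culture did inside a sealed
serum bottle fed with syngas and supplemented acetate. This vignette explains
the model behind each stage, the parameters that matter, what the synthetic
bottle generator does and does not emulate, and the numerical and design
choices that were genuinely open.

## The measurement world

The stated world is a 250 mL serum bottle with 50 mL of broth (`V_Start`),
incubated at 37 or 55 °C and pH-adjusted to 6.7 or 5.5, pressurised to
210 kPa with syngas at partial-pressure proportions 3:20:25 kPa H₂:CO:CO₂
with N₂ as balance, and run for 16 days. Each day 3 mL of headspace is
withdrawn for gas chromatography; every 2 days 1 mL of broth is sampled;
whenever the measured pressure falls below 180 kPa or the CO fraction below
1 %, the bottle is flushed and re-pressurised to 210 kPa with fresh syngas.
Liquid metabolites (formate, acetate, ethanol, propionate, n-butyrate,
n-valerate) are balanced between the first and the last broth sample.

## Gas accounting

The headspace inventory at a state is `n = p·V/(R·T)` (ideal gas; R = 8.314
exactly, no non-ideality at ≤ 2.1 bar), split across the five measured gases
by mole fraction. Micro-GC percentages do not close exactly, so fractions are
renormalised; a deviation of the fraction sum from 1 beyond a tolerance
(default 0.02) is treated as a data error rather than absorbed.

Cumulative consumption/production per species is computed by *interval
differencing*: the sum of `n(end) − n(start)` over consecutive state pairs.
Two corrections make this a biological balance rather than an inventory
curve:

* **Flush resets.** The interval between the pre-flush measurement and the
  post-flush state is excluded; the post-flush state restarts the baseline.
* **Sample valuation.** The 3 mL gas sample is valued at the pressure,
  temperature and composition of the state it was drawn from and added back;
  removed moles are neither consumption nor production. Whether the sample
  was withdrawn at headspace pressure or expanded to ambient is not
  observable from the data; headspace-pressure valuation is the default (the
  alternative would understate the correction by the pressure ratio). A
  sample taken between a measurement and the flush that follows it is
  absorbed by the excluded flush interval.

The headspace volume of the state at time *t* is the bottle volume minus the
broth volume still present, counting liquid withdrawals *before* t — a broth
sample taken at a measurement time affects later states only. N₂ is inert in
every scenario, so its cumulative balance closing on zero is used as an
internal quality-control statistic: exactly zero on noise-free data, and
within ~3 % (1 sd) of the N₂ inventory under 1 % observation noise across the
handful of flush segments of a run; the QC bound is fixed at 10 %.

## Electron and carbon currencies

Electron equivalents follow the degree-of-reduction rule `eeq = 4C + H − 2O`
on the neutral species (dissociation does not move catabolic electrons at
this granularity): CO → 2, H₂ → 2, CH₄ → 8, acetate → 8, n-valerate → 26,
CO₂/N₂ → 0. The test suite checks every registry entry against an
independently balanced oxidation half-reaction. Rates are
`q = n · w / (V_Start · t)` with `w` the electron or carbon weight, in
e-mM/d or C-mM/d; both use the same net mmol, so `q_e/q_C = eeq/C` always.

Liquid net mmol use `V_Start`, not the shrinking broth volume: concentrations
are intensive and the convention deliberately treats withdrawn broth as if it
had stayed, which is also how the rate denominator is normalised. (A
per-sample volume track would change liquid mmol by ≲ 8 % while making rates
and mmol inconsistent with each other; the single-volume convention was
chosen and the simulator states its ground truth in the same convention, so
recovery tests are exact.)

Yields put each product's electrons over the consumed substrate electrons.
"Syngas consumed" is implemented as the summed electron consumption of CO and
H₂, each counted only when net-consumed — the only reading under which a
mixture has a well-defined electron content, and CO₂ is moot at zero eeq. H₂
and acetate switch between substrate and product with the sign of their net
turnover; CH₄, formate, ethanol, propionate, n-butyrate and n-valerate are
always products (a consumed "product" contributes zero yield, keeping yields
non-negative). The electron recovery — the yield sum — may legitimately
exceed 100 %: the bottles contain inoculum solids the balance cannot see.

Control normalisation divides a condition's cumulative e-mol per compound by
the *absolute* control value, preserving sign: a ratio of −2 for CO means
doubled consumption, and a sign change against the control marks a switch
between net production and net consumption. Zero-control compounds are
flagged, never silently divided.

## Speciation

Undissociated acetic acid is `HAc = C_acetate · C_H⁺/(K_a + C_H⁺)` with
`C_H⁺ = 10^-pH`. The two-way g/L ↔ mol/L conversion uses the same molar
mass, which therefore cancels — the function exposes the constant only to
assert that independence. K_a is a two-point lookup (1.70·10⁻⁵ mol/L at
37 °C, 1.58·10⁻⁵ at 55 °C); other temperatures error unless K_a is supplied
explicitly, because interpolating between two assumed constants would suggest
precision the model does not have. pH is the initial adjusted value, held
fixed — the design tables are defined on initial conditions. Comparisons
against printed tables use round-half-away-from-zero at the printed decimal
count, since the tables mix one- and two-decimal cells (e.g. "0.8" next to
"0.74"). One published in-text equivalence (24 g/L acetate at pH 5.5/37 °C
called "5 gHAc/L") is inconsistent with the formula and the table itself
(3.76 g/L) and is not reproduced.

## Thermodynamics

`delta_g()` evaluates `ΔG = ΔG°′ + RT·ln Q` for element-checked reactions,
with water activity 1, protons from pH, dissolved species in mol/L and gases
in bar. Reference energies are *inputs*: published ΔG values for these
reactions derive from reference states that are rarely stated completely, so
the package ships only clearly-labelled approximate examples
(`example_reactions()`) and makes no claim to reproduce specific printed
numbers. No temperature correction beyond the `RT·ln Q` term is applied.

## The synthetic bottle generator

`simulate_bottle()` is a stated world, not a fit. Reactions are
element-balanced stoichiometric conversions (water-gas shift, CO/H₂
acetogenesis, hydrogenotrophic and acetoclastic methanogenesis, syntrophic
acetate oxidation, chain elongation to n-butyrate/n-valerate — all of which
conserve electron equivalents) with zero-order rate constants in mmol per
litre of initial broth per day, integrated with a fixed 0.05 d explicit step
and positivity guards (an extent is capped at the limiting inventory).
Defaults were chosen once from the measurement world: the methanogenic
default (water-gas shift at 4, hydrogenotrophic methanogenesis at 1.5,
acetoclastic methanogenesis at 1.5 mmol/L/d) puts control-bottle CO uptake
near 8 e-mM/d, the magnitude reported for unamended mesophilic controls.

Inhibition by undissociated acetic acid uses an invented, synthetic-only
Hill form `1/(1 + (HAc/K_I)^h)` with h = 2 and K_I = 0.77 gHAc/L, calibrated
once to the literature anchor of ≥ 90 % methanogenesis inhibition at
2.3 gHAc/L (`1/(1+(2.3/K)²) = 0.1 ⇒ K = 2.3/3`). The lag default is 1 d.
Observation noise (default 1 % relative, multiplicative, on pressure,
fractions and concentrations) is applied to *observations only* — the state,
and hence the ground-truth ledger, stays exact, which is what makes the
zero-noise recovery tests meaningful at 10⁻⁹ relative tolerance. Flushing is
an ideal complete headspace exchange at the incubation temperature; the
trigger is evaluated on the true measured state.

What the generator does **not** emulate: microbial growth and community
dynamics, pH drift, dissolved-gas (Henry's law) inventories, Na⁺ inhibition,
residual-gas carryover during flushing, and room-temperature
re-pressurisation. A green recovery test therefore establishes that the
*accounting* is correct under the stated protocol — not that the kinetic
world resembles any particular culture.

## Numerical choices and degenerate inputs

* Units are fixed internally (kPa, mL, K, mmol, d); conversion happens only
  at the edges, because the ideal-gas bookkeeping mixes scales that invite
  10³ errors.
* Intervals with no biology (abiotic controls) balance to machine-precision
  zero; splitting any interval at a measured state leaves totals unchanged
  (tested as a property).
* A gas sample recorded after the final state cannot affect any interval and
  is ignored.
* Abiotic bottles have no consumed substrate electrons; yields are reported
  as an empty set with `NA` recovery rather than an error mid-pipeline.
* Liquid sampling that would drive broth volume to zero, negative pressures,
  unordered events, flushes without a post-flush state, and fraction sums
  outside tolerance are hard validation errors with named offenders.

## Scope and limitations

The package balances the gas phase only; dissolved CO₂/carbonate speciation,
activity coefficients and biomass electron accounting are out of scope —
consistent with recoveries above 100 % being reported, not "corrected".
Statistical comparison between conditions is left to downstream tools; the
package stops at replicate means and standard deviations. Intermediate broth
samples are carried for plotting but do not enter the first/last balance.
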