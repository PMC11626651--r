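test_that("liquid net mmol converts concentration changes with V_Start", {
  spec <- bottle_spec() # 50 mL
  out <- liquid_net_mmol(c(acetate = 12), c(acetate = 4), spec)
  expect_equal(out$n_mmol, (4 - 12) / 60.052 * 0.05 * 1000, tolerance = 1e-12)
  expect_equal(out$n_mmol, -6.66, tolerance = 1e-3)
  out2 <- liquid_net_mmol(c(n_valerate = 0), c(n_valerate = 1.02), spec)
  m_val <- default_registry()$molar_mass[default_registry()$compound ==
                                           "n_valerate"]
  expect_equal(out2$n_mmol, 1.02 / m_val * 0.05 * 1000, tolerance = 1e-12)
  expect_equal(out2$n_mmol, 0.50, tolerance = 1e-2)
  # unchanged concentration -> zero
  expect_equal(liquid_net_mmol(c(ethanol = 1.5), c(ethanol = 1.5),
                               spec)$n_mmol, 0)
  expect_error(liquid_net_mmol(c(unobtainium = 1), c(unobtainium = 2), spec),
               "not in the registry")
})

test_that("electron- and carbon-mole rates scale by eeq/carbon over V_Start x t", {
  spec <- bottle_spec()
  expect_equal(emol_rate(-10, "CO", spec, 16), -10 * 2 / (0.05 * 16))
  expect_equal(emol_rate(-10, "CO", spec, 16), -25)
  expect_equal(emol_rate(4, "CH4", spec, 16), 40)
  expect_equal(emol_rate(0, "acetate", spec, 16), 0)
  expect_equal(cmol_rate(-10, "CO", spec, 16), -12.5)
  expect_equal(cmol_rate(3, "acetate", spec, 16), 7.5)
  expect_equal(cmol_rate(99, "H2", spec, 16), 0) # carbon-free
  expect_error(emol_rate(1, "CO", spec, 0), "t_total")
})

test_that("e-mol and C-mol rates stay in the eeq/carbon ratio", {
  spec <- bottle_spec()
  reg <- default_registry()
  carbon_bearing <- reg$compound[reg$carbon > 0]
  set.seed(11)
  for (cmp in carbon_bearing) {
    n <- runif(1, -20, 20)
    row <- reg[reg$compound == cmp, ]
    expect_equal(emol_rate(n, cmp, spec, 16) / cmol_rate(n, cmp, spec, 16),
                 row$eeq / row$carbon, info = cmp)
  }
})

test_that("product yields balance product electrons against consumed substrate electrons", {
  # CH4 carrying exactly the CO electrons -> 100%
  full <- product_yields(tibble::tibble(compound = c("CO", "CH4"),
                                        n_mmol = c(-10, 2.5)))
  expect_equal(full$yields$yield_pct, 100)
  expect_equal(full$electron_recovery_pct, 100)
  # CH4 + acetate at 40% each
  two <- product_yields(tibble::tibble(compound = c("CO", "CH4", "acetate"),
                                       n_mmol = c(-10, 1, 1)))
  expect_equal(sort(two$yields$yield_pct), c(40, 40))
  expect_equal(two$electron_recovery_pct, 80)
  # no products -> zero yields, zero recovery
  none <- product_yields(tibble::tibble(compound = c("CO"), n_mmol = c(-10)))
  expect_equal(nrow(none$yields), 0)
  expect_equal(none$electron_recovery_pct, 0)
  expect_error(product_yields(tibble::tibble(compound = "CH4", n_mmol = 2)),
               "no substrate")
})

test_that("H2 and acetate switch roles across zero net turnover", {
  for (eps in c(2, 0.5, 1e-6)) {
    flows_cons <- assign_roles(tibble::tibble(
      compound = c("CO", "acetate", "H2", "CH4"),
      n_mmol = c(-10, -eps, -eps, 3)
    ))
    expect_equal(flows_cons$role[flows_cons$compound == "acetate"],
                 "substrate")
    expect_equal(flows_cons$role[flows_cons$compound == "H2"], "substrate")
    flows_prod <- assign_roles(tibble::tibble(
      compound = c("CO", "acetate", "H2", "CH4"),
      n_mmol = c(-10, eps, eps, 3)
    ))
    expect_equal(flows_prod$role[flows_prod$compound == "acetate"], "product")
    expect_equal(flows_prod$role[flows_prod$compound == "H2"], "product")
    # yields stay finite and non-negative on both sides of the switch
    for (fl in list(flows_cons, flows_prod)) {
      py <- product_yields(fl)
      expect_true(all(is.finite(py$yields$yield_pct)))
      expect_true(all(py$yields$yield_pct >= 0))
    }
  }
  # CH4 and the carboxylates are products regardless of sign
  always <- assign_roles(tibble::tibble(
    compound = c("CH4", "formate", "ethanol", "n_butyrate"),
    n_mmol = c(-1, -1, -1, -1)
  ))
  expect_true(all(always$role == "product"))
})

test_that("control normalisation preserves sign and flags zero controls", {
  cond <- tibble::tibble(compound = c("CO", "acetate", "CH4"),
                         e_mmol = c(-16.2, -4, 0.5))
  ctrl <- tibble::tibble(compound = c("CO", "acetate", "CH4"),
                         e_mmol = c(-8.1, 2, 0))
  out <- normalize_to_control(cond, ctrl)
  expect_equal(out$ratio[out$compound == "CO"], -2) # doubled consumption
  # consumption in condition vs production in control -> negative ratio
  expect_equal(out$ratio[out$compound == "acetate"], -2)
  expect_true(out$zero_control[out$compound == "CH4"])
  expect_true(is.na(out$ratio[out$compound == "CH4"]))
  # self-normalisation gives +/-1
  self <- normalize_to_control(ctrl[1:2, ], ctrl[1:2, ])
  expect_equal(self$ratio, c(-1, 1))
})

test_that("replicate aggregation uses the n-1 standard deviation", {
  out <- aggregate_replicates(c(8.0, 8.1, 8.2))
  expect_equal(out$mean, 8.1)
  expect_equal(out$sd, 0.1)
  expect_equal(aggregate_replicates(c(5, 5, 5))$sd, 0)
  expect_equal(aggregate_replicates(c(-25, -25, -25))$mean, -25)
  single <- aggregate_replicates(3.2)
  expect_true(is.na(single$sd))
  expect_equal(single$n, 1)
})
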