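test_that("an abiotic control changes only through sampling", {
  sim <- simulate_bottle(bottle_spec(), scenario_abiotic(noise = zero_noise))
  bal <- analyze_bottle(sim$gas, sim$events, sim$liquid, sim$spec)
  expect_true(all(abs(bal$flows$n_mmol) < 1e-10))
  expect_true(all(sim$truth$flows$n_mmol == 0))
  # pressure strictly decreases between flushes (sampling only)
  measures <- sim$gas[sim$gas$event == "measure", ]
  expect_lt(measures$pressure_kPa[2], measures$pressure_kPa[1])
})

test_that("hydrogenogenesis-only bottles convert CO to H2 and CO2 1:1:1", {
  sc <- ferm_scenario(list(rxn_hydrogenogenesis(4)), noise = zero_noise,
                      lag_d = 0)
  sim <- simulate_bottle(bottle_spec(), sc)
  truth <- setNames(sim$truth$flows$n_mmol, sim$truth$flows$compound)
  expect_lt(truth[["CO"]], 0)
  expect_equal(-truth[["CO"]], truth[["H2"]])
  expect_equal(-truth[["CO"]], truth[["CO2"]])
  expect_equal(truth[["N2"]], 0)
})

test_that("flushes fire on the stated triggers and restore the refill composition", {
  sc <- ferm_scenario(list(rxn_hydrogenogenesis(8)), noise = zero_noise,
                      lag_d = 0)
  sim <- simulate_bottle(bottle_spec(), sc)
  expect_gt(sim$truth$n_flushes, 0)
  post <- sim$gas[sim$gas$event == "post_flush", ]
  expect_equal(post$x_CO, rep(20 / 210, nrow(post)))
  expect_equal(post$x_H2, rep(3 / 210, nrow(post)))
  expect_equal(post$pressure_kPa, rep(210, nrow(post)))
  # trigger iff measured pressure < 180 kPa or CO fraction < 1%
  measures <- sim$gas[sim$gas$event == "measure", ]
  flush_days <- sim$events$time_d[sim$events$kind == "flush"]
  should <- measures$time_d[measures$pressure_kPa < 180 |
                              measures$x_CO < 0.01]
  expect_setequal(flush_days, should)
})

test_that("undissociated-acid inhibition suppresses methanogenesis at low pH", {
  base <- function(pH) {
    sc <- ferm_scenario(list(rxn_acetoclastic_methanogenesis(1.5)),
                        K_I = 1, hill = 2, lag_d = 0, noise = zero_noise)
    spec <- bottle_spec(acetate_gL = 12, pH = pH, temp_C = 55)
    sim <- simulate_bottle(spec, sc)
    sim$truth$flows$n_mmol[sim$truth$flows$compound == "CH4"]
  }
  ch4_67 <- base(6.7)
  ch4_55 <- base(5.5)
  # HAc is 2.0 g/L at pH 5.5 but 0.15 g/L at pH 6.7: >= 4-fold suppression
  expect_gt(ch4_67 / ch4_55, 4)
})

test_that("zero-noise pipelines recover the simulated ground truth exactly", {
  for (cond in list(c(0, 6.7, 37), c(12, 6.7, 37), c(48, 5.5, 55))) {
    spec <- bottle_spec(acetate_gL = cond[1], pH = cond[2], temp_C = cond[3])
    sim <- simulate_bottle(spec, scenario_methanogenic(noise = zero_noise))
    bal <- analyze_bottle(sim$gas, sim$events, sim$liquid, sim$spec)
    m <- dplyr::inner_join(bal$flows, sim$truth$flows, by = "compound",
                           suffix = c("", "_true"))
    expect_equal(m$n_mmol, m$n_mmol_true, tolerance = 1e-11)
    expect_equal(m$q_emol, m$q_emol_true, tolerance = 1e-11)
  }
})

test_that("noise-free electron-conserving scenarios close the electron balance", {
  sc <- ferm_scenario(
    list(rxn_hydrogenogenesis(4), rxn_hydrogenotrophic_methanogenesis(1.5),
         rxn_acetoclastic_methanogenesis(1.5),
         rxn_chain_elongation_butyrate(0.3)),
    noise = zero_noise
  )
  sim <- simulate_bottle(bottle_spec(acetate_gL = 8, pH = 6.7, temp_C = 37),
                         sc)
  expect_equal(sim$truth$electron_recovery_pct, 100, tolerance = 1e-9)
  bal <- analyze_bottle(sim$gas, sim$events, sim$liquid, sim$spec)
  expect_equal(bal$electron_recovery_pct, 100, tolerance = 1e-9)
})

test_that("simulations are reproducible under a fixed seed", {
  spec <- bottle_spec(acetate_gL = 4)
  a <- simulate_bottle(spec, scenario_methanogenic(seed = 99))
  b <- simulate_bottle(spec, scenario_methanogenic(seed = 99))
  c <- simulate_bottle(spec, scenario_methanogenic(seed = 100))
  expect_identical(a$gas, b$gas)
  expect_identical(a$liquid, b$liquid)
  expect_false(identical(a$gas$pressure_kPa, c$gas$pressure_kPa))
})

test_that("the experiment grid enumerates the full design with distinct seeds", {
  grid <- make_experiment_grid()
  expect_equal(nrow(grid), 14 * 2 * 2 * 3)
  expect_equal(anyDuplicated(grid$seed), 0)
  # zero-acetate control in every pH x temperature stratum
  strata <- dplyr::distinct(grid[, c("pH", "temp_C")])
  for (i in seq_len(nrow(strata))) {
    expect_true(any(grid$acetate_gL == 0 & grid$pH == strata$pH[i] &
                      grid$temp_C == strata$temp_C[i]))
  }
  small <- make_experiment_grid(acetate_gL = c(0, 12), pH = 6.7, temp_C = 37,
                                replicates = 3)
  sims <- simulate_experiment(small)
  expect_length(sims, 6)
  expect_s3_class(sims[[1]], "bottle_sim")
})
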