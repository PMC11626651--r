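test_that("headspace amounts match the SI-unit ideal-gas oracle", {
  cases <- list(c(210, 200, 298.15), c(180, 205, 310.15), c(95, 208, 328.15))
  for (cs in cases) {
    expect_equal(headspace_moles(cs[1], cs[2], cs[3]),
                 oracle_ideal_gas_mmol(cs[1], cs[2], cs[3]))
  }
  expect_equal(headspace_moles(210, 200, 298.15), 16.94, tolerance = 1e-3)
  expect_equal(headspace_moles(0, 200, 298.15), 0)
  # linearity in volume
  expect_equal(headspace_moles(210, 400, 298.15),
               2 * headspace_moles(210, 200, 298.15))
  expect_error(headspace_moles(210, -1, 298.15), "volume")
})

test_that("species amounts split by mole fraction and close on the total", {
  state <- tibble::tibble(pressure_kPa = 210, temp_K = 298.15,
                          x_CO = 0.2, x_CO2 = 0.25, x_H2 = 0.05,
                          x_CH4 = 0, x_N2 = 0.5)
  sp <- species_moles(state, 200)
  total <- headspace_moles(210, 200, 298.15)
  expect_equal(sp[["CO"]], 0.2 * total)
  expect_equal(sp[["CH4"]], 0)
  expect_equal(sum(sp), total, tolerance = 1e-12)
})

test_that("trajectory validation renormalises fractions and tracks headspace volume", {
  gas <- tibble::tibble(
    time_d = seq(0, 16, by = 2), pressure_kPa = 210,
    x_CO = 0.2 * 1.01, x_CO2 = 0.25 * 1.01, x_H2 = 0.05 * 1.01,
    x_CH4 = 0, x_N2 = 0.5 * 1.01
  )
  events <- tibble::tibble(
    time_d = seq(0, 16, by = 2), kind = "liquid_sample", volume_mL = 1
  )
  traj <- validate_trajectory(gas, events, bottle_spec())
  expect_equal(rowSums(traj$states[, c("x_CO", "x_CO2", "x_H2", "x_CH4",
                                       "x_N2")]),
               rep(1, 9))
  # 250 - 50 initially; +1 mL per prior liquid sample; day-16 sample not yet
  expect_equal(traj$states$headspace_mL, 200:208)
})

test_that("trajectory validation rejects malformed input", {
  gas <- make_simple_gas()
  expect_error(validate_trajectory(gas[1, ], NULL, bottle_spec()),
               "at least two")
  bad <- gas
  bad$pressure_kPa[1] <- -5
  expect_error(validate_trajectory(bad, NULL, bottle_spec()), "pressure")
  off <- gas
  off$x_N2 <- off$x_N2 + 0.05 # fraction sum 1.05 > tolerance
  expect_error(validate_trajectory(off, NULL, bottle_spec()), "mole-fraction")
  ev <- tibble::tibble(time_d = 99, kind = "gas_sample", volume_mL = 3)
  expect_error(validate_trajectory(gas, ev, bottle_spec()), "time span")
  fl <- tibble::tibble(time_d = 16, kind = "flush", volume_mL = 200)
  expect_error(validate_trajectory(gas, fl, bottle_spec()), "post_flush")
  drain <- tibble::tibble(time_d = c(0, 5), kind = "liquid_sample",
                          volume_mL = c(30, 30))
  expect_error(validate_trajectory(gas, drain, bottle_spec()), "<= 0")
})

test_that("event-free balances equal endpoint differences (oracle equivalence)", {
  gas <- make_simple_gas(times = c(0, 4, 9, 16),
                         pressures = c(210, 200, 195, 190),
                         x_CO = c(0.2, 0.17, 0.13, 0.1))
  spec <- bottle_spec()
  bal <- cumulative_balance(gas, NULL, spec)
  traj <- validate_trajectory(gas, NULL, spec)
  n_first <- species_moles(traj$states[1, ], traj$states$headspace_mL[1])
  n_last <- species_moles(traj$states[4, ], traj$states$headspace_mL[4])
  expect_equal(setNames(bal$n_mmol, bal$compound), n_last - n_first)
  # CO dropped: consumption is negative
  expect_lt(bal$n_mmol[bal$compound == "CO"], 0)
})

test_that("splitting an interval at a measured state leaves the balance unchanged", {
  spec <- bottle_spec()
  coarse <- make_simple_gas(times = c(0, 16), pressures = c(210, 190),
                            x_CO = c(0.2, 0.1))
  set.seed(42)
  for (rep in 1:10) {
    t_mid <- runif(1, 0.5, 15.5)
    p_mid <- runif(1, 185, 215)
    x_mid <- runif(1, 0.05, 0.25)
    fine <- make_simple_gas(times = c(0, t_mid, 16),
                            pressures = c(210, p_mid, 190),
                            x_CO = c(0.2, x_mid, 0.1))
    expect_equal(cumulative_balance(fine, NULL, spec),
                 cumulative_balance(coarse, NULL, spec))
  }
})

test_that("a flush between identical pre/post states contributes nothing", {
  gas <- make_simple_gas(times = c(0, 8, 8, 16),
                         pressures = c(210, 200, 200, 190),
                         x_CO = c(0.2, 0.15, 0.15, 0.1))
  gas$event <- c("measure", "measure", "post_flush", "measure")
  events <- tibble::tibble(time_d = 8, kind = "flush", volume_mL = 200)
  no_flush <- make_simple_gas(times = c(0, 8, 16),
                              pressures = c(210, 200, 190),
                              x_CO = c(0.2, 0.15, 0.1))
  expect_equal(cumulative_balance(gas, events, bottle_spec()),
               cumulative_balance(no_flush, NULL, bottle_spec()))
})

test_that("flush resets the baseline so exchanged gas is not biology", {
  # post-flush state back to fresh syngas: only within-segment changes count
  gas <- tibble::tibble(
    time_d = c(0, 8, 8, 16),
    event = c("measure", "measure", "post_flush", "measure"),
    pressure_kPa = c(210, 185, 210, 190),
    x_CO = c(20, 2, 20, 5) / 210,
    x_CO2 = 0.25, x_H2 = 0.05,
    x_CH4 = c(0, 0.04, 0, 0.03),
    x_N2 = 1 - c(20, 2, 20, 5) / 210 - 0.25 - 0.05 - c(0, 0.04, 0, 0.03)
  )
  events <- tibble::tibble(time_d = 8, kind = "flush", volume_mL = 200)
  spec <- bottle_spec()
  bal <- cumulative_balance(gas, events, spec)
  traj <- validate_trajectory(gas, events, spec)
  n <- lapply(1:4, function(i) {
    species_moles(traj$states[i, ], traj$states$headspace_mL[i])
  })
  manual <- (n[[2]] - n[[1]]) + (n[[4]] - n[[3]])
  expect_equal(setNames(bal$n_mmol, bal$compound), manual)
})

test_that("a 3 mL sample on an abiotic bottle balances to zero after correction", {
  spec <- bottle_spec()
  v <- 200
  p0 <- 200
  # after removing 3 mL at headspace pressure, inventory drops by 3/200
  p1 <- p0 * (1 - 3 / v)
  gas <- make_simple_gas(times = c(0, 1), pressures = c(p0, p1),
                         x_CO = c(0.2, 0.2))
  events <- tibble::tibble(time_d = 0, kind = "gas_sample", volume_mL = 3)
  bal <- cumulative_balance(gas, events, spec)
  expect_equal(bal$n_mmol, rep(0, 5), tolerance = 1e-12)
  # without the correction the drop would be misread as consumption
  bal_raw <- cumulative_balance(gas, NULL, spec)
  expect_lt(bal_raw$n_mmol[bal_raw$compound == "CO"], 0)
})
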