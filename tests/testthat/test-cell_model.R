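test_that("the state layout manifest is consistent and packing is lossless", {
  lay <- state_layout()
  expect_equal(lay$n_state, length(lay$names))
  expect_equal(length(lay$tubular), 27)
  expect_equal(length(lay$cleft), 3)
  y <- fx_rest()
  expect_named(y, lay$names)
  rhs <- assemble_rhs(y, default_parameters())
  expect_named(rhs$derivatives, lay$names)
  expect_named(rhs$aux, aux_names())
})

test_that("clamping all extracellular compartments zeroes their 30 derivatives", {
  p <- default_parameters()
  y <- fx_rest()
  lay <- state_layout()
  rhs <- assemble_rhs(y, p, clamp_config("clamp_all_extracellular"),
                      stim_amp = -1800)
  extr <- c(lay$tubular, lay$cleft)
  expect_length(extr, 30)
  expect_equal(unname(rhs$derivatives[extr]), rep(0, 30))
  # cleft-only clamp leaves the tubular shells dynamic
  rhs2 <- assemble_rhs(y, p, clamp_config("clamp_cleft"), stim_amp = -1800)
  expect_equal(unname(rhs2$derivatives[lay$cleft]), rep(0, 3))
  # dialysed mode pins intracellular Na+ and K+
  rhs3 <- assemble_rhs(y, p, clamp_config("fix_intracellular_NaK"))
  expect_equal(unname(rhs3$derivatives[c("na_i", "k_i")]), c(0, 0))
})

test_that("intracellular Na+ bookkeeping matches the summed Na+ currents", {
  p <- default_parameters()
  for (v in c(-84, -40, 0, 20)) {
    y <- fx_rest(); y["v"] <- v
    rhs <- assemble_rhs(y, p)
    led <- species_currents(y, p)
    i_na <- sum(led$i_charge[led$species == "Na"])
    expected <- -i_na / (96485 * p$v_myo)
    expect_lt(abs(rhs$derivatives[["na_i"]] - expected) /
                max(abs(expected), 1e-12), 1e-9)
  }
})

test_that("invalid states are rejected with a diagnostic", {
  y <- fx_rest()
  y["ca_i"] <- -1e-5
  expect_error(assemble_rhs(y, default_parameters()), "non-positive")
})

test_that("a zero-amplitude protocol leaves the quiescent state unchanged", {
  p <- default_parameters()
  y <- fx_rest()
  pr <- pacing_protocol(c(1, 5), stim_amp = 0)
  sim <- simulate_model(y, p, pr)
  keep <- setdiff(state_layout()$names, state_layout()$accumulators)
  expect_equal(sim$final_state[keep], y[keep], tolerance = 1e-5)
})

test_that("per-cycle Eq-style Ca2+ flux columns are consistent and finite", {
  cyc <- fx_paced()$cycles
  expect_true(all(is.finite(unlist(cyc))))
  expect_equal(nrow(cyc), 10)
  # quadrature accumulators agree with the trapezoid oracle on the stored trace
  tr <- last_cycle_trace(fx_paced())
  n_t_oracle <- cycle_ca_balance(tr, "tubular")
  expect_equal(n_t_oracle, cyc$n_ca_net_t[10], tolerance = 0.02)
})

test_that("refining solver tolerances leaves APD90 essentially unchanged", {
  p <- default_parameters()
  y <- fx_rest()
  apd_at <- function(rtol, atol_scale) {
    sim <- simulate_model(y, p, pacing_protocol(c(1, 8)), record = 8,
                          sample_ms = 0.5, rtol = rtol,
                          atol_scale = atol_scale)
    apd(last_cycle_trace(sim), 0.9)
  }
  a1 <- apd_at(1e-6, 1)
  a2 <- apd_at(5e-7, 0.5)
  expect_lt(abs(a1 - a2), 0.5)
})
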