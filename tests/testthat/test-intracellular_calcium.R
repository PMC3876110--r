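test_that("buffer occupancancy follows mass-action equilibrium", {
  p <- default_parameters()
  y <- fx_rest()
  # at c = Kd the equilibrium occupancy is one half
  kd_cm <- p$cmdn_koff / p$cmdn_kon
  y["ca_i"] <- kd_cm
  bf <- buffer_fluxes(y, p)
  expect_equal(bf$occupancy_eq[bf$buffer == "calmodulin"], 0.5)
  # arbitrary ligand level: occupancy_eq = c / (c + Kd) for every buffer
  for (c in c(1e-5, 2e-4, 0.5)) {
    y2 <- fx_rest(); y2["ca_i"] <- c; y2["ca_jsr"] <- c
    bf2 <- buffer_fluxes(y2, p)
    expect_equal(bf2$occupancy_eq, bf2$ligand / (bf2$ligand + bf2$kd))
  }
  # flux vanishes when bound concentration equals its equilibrium value
  y3 <- fx_rest()
  y3["b_cm"] <- p$cmdn_tot * y3[["ca_i"]] / (y3[["ca_i"]] + kd_cm)
  expect_equal(buffer_fluxes(y3, p)$flux[1], 0, tolerance = 1e-15)
})

test_that("free plus bound buffer is conserved along a paced trajectory", {
  tr <- fx_paced()$trace
  p <- default_parameters()
  # bound never exceeds the total, never negative
  expect_true(all(tr$b_cm >= 0 & tr$b_cm <= p$cmdn_tot))
  expect_true(all(tr$b_htrpn >= 0 & tr$b_htrpn <= p$htrpn_tot))
  expect_true(all(tr$b_ltrpn >= 0 & tr$b_ltrpn <= p$ltrpn_tot))
  expect_true(all(tr$b_cs >= 0 & tr$b_cs <= p$csqn_tot))
})

test_that("SR fluxes have the expected zeros and monotonicity", {
  p <- default_parameters()
  y <- fx_rest()
  # no NSR-JSR gradient, no transfer
  y["ca_jsr"] <- y[["ca_nsr"]]
  expect_equal(sr_fluxes(y, p)$j_tr, 0, tolerance = 1e-15)
  # fully closed RyR releases nothing
  y2 <- fx_rest()
  y2[c("ryr_o1", "ryr_o2")] <- 0
  y2[c("ryr_c1", "ryr_c2")] <- c(1, 0)
  expect_equal(sr_fluxes(y2, p)$j_rel, 0, tolerance = 1e-15)
  # uptake is monotone non-decreasing in cytosolic Ca2+ over the
  # physiological range (numeric check on a grid)
  grid <- 10^seq(log10(2e-5), log10(2e-3), length.out = 25)
  jup <- vapply(grid, function(c) {
    y3 <- fx_rest(); y3["ca_i"] <- c
    sr_fluxes(y3, p)$j_up
  }, numeric(1))
  expect_true(all(diff(jup) >= 0))
})

test_that("intracellular Ca2+ changes only through sarcolemmal flux on a paced cycle", {
  # cycle-integrated audit: total cell Ca2+ change equals the integral of
  # the Ca2+-carried membrane currents, within 0.1% of the gross turnover
  sim <- fx_paced()
  p <- default_parameters()
  tr <- last_cycle_trace(sim)
  vsh <- shell_volumes(p)
  total_ca <- function(row) {
    p$v_myo * (row$ca_i + row$b_cm + row$b_htrpn + row$b_ltrpn) +
      p$v_ds * row$ca_d + p$v_nsr * row$ca_nsr +
      p$v_jsr * (row$ca_jsr + row$b_cs)
  }
  d_content <- total_ca(tr[nrow(tr), ]) - total_ca(tr[1, ])  # fmol
  ica <- with(tr, i_cal_s + i_cal_t + i_bca_s + i_bca_t +
                i_pca_s + i_pca_t - 2 * (i_naca_s + i_naca_t))
  influx <- -sum(diff(tr$time) * (head(ica, -1) + tail(ica, -1)) / 2) /
    (2 * 96485)  # fmol
  gross <- sum(diff(tr$time) * abs(head(ica, -1) + tail(ica, -1)) / 2) /
    (2 * 96485)
  expect_lt(abs(d_content - influx), 0.001 * gross)
})

test_that("the quiescent model rests near the reported diastolic Ca2+ level", {
  y <- fx_rest()
  expect_equal(y[["ca_i"]] * 1e6, 63.6, tolerance = 0.05)
  # a further minute of unstimulated integration barely moves the membrane
  pv <- ttmyo:::param_vector(default_parameters())
  pv["stim_amp"] <- 0
  sp <- ttmyo:::.integrate_span(y, 0, 60000, pv)
  expect_lt(abs(sp$y_end[["v"]] - y[["v"]]), 0.1)
})
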