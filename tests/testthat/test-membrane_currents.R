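test_that("Nernst potential matches the closed form and its scalings", {
  expect_equal(reversal_potential(1, 5.4, 5.4), 0)
  # monovalent cation, 5.4 mM out / 130 mM in at 310 K
  expect_equal(reversal_potential(1, 5.4, 130), -84.9, tolerance = 2e-3)
  # doubling the valence halves the magnitude at a fixed ratio
  expect_equal(reversal_potential(2, 10, 1), reversal_potential(1, 10, 1) / 2)
  expect_error(reversal_potential(1, -1, 5), "positive")
  expect_error(reversal_potential(2, 2, 0), "positive")
})

test_that("tubular components vanish when all t-tubular fractions are zero", {
  p <- default_parameters()
  for (f in grep("^f_", names(unclass(p)), value = TRUE)) p[[f]] <- 0
  mc <- membrane_currents(fx_rest(), p)
  expect_true(all(abs(mc$current[mc$pool == "tubular"]) < 1e-12))
})

test_that("with identical local concentrations conductance currents split by f_x_t", {
  p <- default_parameters()
  y <- fx_rest()
  # equalize both pools' local concentrations
  y[paste0("ca_t", 1:9)] <- y[["ca_c"]]
  y[paste0("k_t", 1:9)] <- y[["k_c"]]
  y[paste0("na_t", 1:9)] <- y[["na_c"]]
  mc <- membrane_currents(y, p)
  wide <- tidyr::pivot_wider(mc, names_from = "pool", values_from = "current")
  fr <- c(i_na = p$f_na_t, i_cal = p$f_cal_t, i_kto = p$f_kto_t,
          i_kr = p$f_kr_t, i_ks = p$f_ks_t, i_k1 = p$f_k1_t,
          i_naca = p$f_naca_t, i_nak = p$f_nak_t, i_pca = p$f_pca_t,
          i_bca = p$f_cab_t, i_bna = p$f_bna_t, i_kna = p$f_kna_t)
  for (fam in names(fr)) {
    row <- wide[wide$family == fam, ]
    tot <- row$surface + row$tubular
    if (abs(tot) > 1e-9)
      expect_equal(row$tubular / tot, unname(fr[fam]), tolerance = 1e-9,
                   label = paste("split of", fam))
  }
})

test_that("the species charge ledger sums exactly to the total ionic current", {
  for (y in list(fx_rest(), {
    y2 <- fx_rest(); y2["v"] <- -20; y2["ca_i"] <- 5e-4; y2
  })) {
    rhs <- assemble_rhs(y, default_parameters())
    led <- species_currents(y, default_parameters())
    expect_lt(abs(sum(led$i_charge) - rhs$aux[["i_tot"]]), 1e-9)
  }
})

test_that("the inward rectifier reverses sign at the local K+ equilibrium", {
  p <- default_parameters()
  y <- fx_rest()
  ek <- reversal_potential(1, y[["k_c"]], y[["k_i"]])
  i_at <- function(v) {
    y2 <- y; y2["v"] <- v
    assemble_rhs(y2, p)$aux[["i_k1_s"]]
  }
  expect_lt(i_at(ek - 2), 0)
  expect_gt(i_at(ek + 2), 0)
  expect_equal(i_at(ek), 0, tolerance = 1e-6)
})

test_that("Markov chains conserve probability instantaneously and over time", {
  p <- default_parameters()
  y <- fx_rest()
  d <- gating_derivatives(y, p)
  lay <- state_layout()
  for (chain in names(lay$markov))
    expect_equal(sum(d[lay$markov[[chain]]]), 0, tolerance = 1e-12,
                 label = paste("conservation of", chain))
  # along a paced trajectory the occupancy sums must not drift
  tr <- fx_paced()$trace
  for (chain in names(lay$markov)) {
    s <- rowSums(tr[, lay$markov[[chain]]])
    expect_lt(max(abs(s - 1)), 1e-6)
  }
})

test_that("integrated Markov occupancies match the rate-matrix null space", {
  p <- default_parameters()
  y <- fx_rest()
  y["v"] <- -30  # partially activated operating point
  q <- markov_matrix("na_activation", y, p)
  expect_equal(colSums(q), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  eq <- markov_equilibrium("na_activation", y, p)
  # independent oracle: integrate the linear chain to equilibrium
  occ <- c(1, 0, 0, 0)
  dt <- 0.005
  for (i in 1:20000) occ <- occ + dt * as.numeric(q %*% occ)
  expect_equal(unname(eq), occ, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("a Hodgkin-Huxley gate at its steady state has zero derivative", {
  p <- default_parameters()
  y <- fx_rest()
  y["v"] <- -25
  # bisect kto_r to its fixed point at this voltage using the model itself
  d_of <- function(r) {
    y2 <- y; y2["kto_r"] <- r
    gating_derivatives(y2, p)[["kto_r"]]
  }
  lo <- 0; hi <- 1
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (d_of(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(d_of((lo + hi) / 2), 0, tolerance = 1e-10)
})
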