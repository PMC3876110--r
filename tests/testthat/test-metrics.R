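test_that("APD on a triangular pulse matches the closed form", {
  # symmetric triangle: 50 ms rise from -80 to +20, 50 ms fall back
  tt <- seq(0, 120, by = 0.05)
  v <- ifelse(tt <= 10, -80,
              ifelse(tt <= 60, -80 + (tt - 10) * 2,
                     pmax(20 - (tt - 60) * 2, -80)))
  tr <- data.frame(time = tt, v = v)
  # upstroke at max dV/dt (start of the ramp), APD90 at 90% repolarization:
  # crossing of -80 + 0.1*100 on the falling limb, i.e. 45 ms after peak
  expect_equal(apd(tr, 0.9), (60 - 10) + 0.9 * 100 / 2, tolerance = 0.2)
  expect_equal(apd(tr, 0.5), (60 - 10) + 0.5 * 100 / 2, tolerance = 0.2)
  # time-shift invariance
  tr2 <- tr; tr2$time <- tr2$time + 1234.5
  expect_lt(abs(apd(tr2, 0.9) - apd(tr, 0.9)), 0.1)
  # no AP: flat trace yields the explicit marker, not zero
  flat <- data.frame(time = tt, v = rep(-80, length(tt)))
  expect_true(is.na(apd(flat, 0.9)))
  expect_equal(attr(apd(flat, 0.9), "reason"), "no_ap")
})

test_that("APD is stable under sampling refinement", {
  p <- default_parameters()
  sim1 <- simulate_model(fx_rest(), p, pacing_protocol(c(1, 3)),
                         record = 3, sample_ms = 1)
  sim2 <- simulate_model(fx_rest(), p, pacing_protocol(c(1, 3)),
                         record = 3, sample_ms = 0.1)
  expect_lt(abs(apd(last_cycle_trace(sim1), 0.9) -
                  apd(last_cycle_trace(sim2), 0.9)), 0.1)
})

test_that("transient area change follows its definition", {
  expect_equal(transient_area_change(1, 1), 0)
  expect_equal(transient_area_change(0.97, 1), -3)
  # antisymmetry relation: swapping arguments maps x-1 to 1/x-1
  x <- 0.85
  expect_equal(transient_area_change(x, 1) / 100 + 1,
               1 / (transient_area_change(1, x) / 100 + 1))
  s <- fx_paced()
  expect_error(transient_area_change(s, {
    s2 <- s; s2$cycles$t_end <- s2$cycles$t_end + 0.1; s2
  }), "cycle length")
})

test_that("cycle Ca2+ balance integrates currents with the stated units", {
  # constant I_CaL = I0 with the other currents zero: n = I0*T/(2F)
  T <- 1000; I0 <- -200
  tr <- data.frame(time = seq(0, T, by = 1),
                   i_cal_s = I0, i_naca_s = 0, i_bca_s = 0, i_pca_s = 0)
  n <- cycle_ca_balance(tr, "surface", period = T)
  expect_equal(n, I0 * T * 1e3 / (2 * 96485), tolerance = 1e-12)
  # all-zero currents give exactly zero
  tr0 <- tr; tr0$i_cal_s <- 0
  expect_equal(cycle_ca_balance(tr0, "surface"), 0)
  # incomplete cycles are rejected
  expect_error(cycle_ca_balance(tr[1:500, ], "surface", period = T), "period")
  # agreement with an inline trapezoid oracle on a stored model trace
  trm <- last_cycle_trace(fx_paced())
  integ <- trm$i_cal_t - 2 * trm$i_naca_t + trm$i_bca_t + trm$i_pca_t
  oracle <- sum(diff(trm$time) * (head(integ, -1) + tail(integ, -1)) / 2) *
    1e3 / (2 * 96485)
  expect_equal(cycle_ca_balance(trm, "tubular"), oracle, tolerance = 1e-6)
})

test_that("end-diastolic series bookkeeping matches delivered stimuli", {
  sim <- fx_paced()
  ed <- end_diastolic_series(sim)
  expect_equal(nrow(ed), nrow(sim$cycles))
  expect_true(all(c("cycle", "t_end", "k_c_end") %in% names(ed)))
  # constant series for a constant signal
  ed2 <- end_diastolic_series(tibble::tibble(cycle = 1:5, t_end = 1:5,
                                             v_end = rep(-84, 5)), "v_end")
  expect_equal(unique(ed2$v_end), -84)
})

test_that("exponential fits recover known time constants", {
  tt <- seq(0, 200, by = 2)
  fit <- fit_exponential_tau(data.frame(t = tt, y = 0.5 + 2 * exp(-tt / 46)),
                             "decay")
  expect_equal(fit$tau, 46, tolerance = 0.01)
  # rising saturation
  fit_r <- fit_exponential_tau(data.frame(t = tt, y = 3 - 1.5 * exp(-tt / 10)),
                               "all")
  expect_equal(fit_r$tau, 10, tolerance = 0.01)
  expect_error(fit_exponential_tau(data.frame(t = 1:3, y = 1:3)), "5 points")
})

test_that("noisy exponential recovery succeeds for 95% of seeds", {
  tau_true <- 46
  tt <- seq(0, 250, length.out = 100)
  ok <- vapply(1:40, function(seed) {
    set.seed(seed)
    y <- 1 + 2 * exp(-tt / tau_true)
    y <- y + rnorm(length(y), 0, 0.01 * diff(range(y)))
    fit <- fit_exponential_tau(data.frame(t = tt, y = y), "decay")
    abs(fit$tau - tau_true) / tau_true < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
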