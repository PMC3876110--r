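test_that("radial diffusion has the right zeros and conserves luminal mass", {
  p <- default_parameters()
  # uniform profile: nothing moves
  expect_equal(radial_diffusion_rhs(rep(2, 9), p, "ca"), rep(0, 9))
  # telescoping conservation: volume-weighted derivatives sum to zero
  set.seed(42)
  for (i in 1:20) {
    prof <- runif(9, 0.5, 3)
    d <- radial_diffusion_rhs(prof, p, sample(c("ca", "k", "na"), 1))
    vsh <- shell_volumes(p)
    expect_equal(sum(d * vsh), 0, tolerance = 1e-12 * sum(abs(d * vsh) + 1))
  }
})

test_that("the 2-shell reduction relaxes at the analytic eigenvalue", {
  p <- default_parameters()
  # two shells of a cylinder: conductance g across the single interface,
  # eigenvalue of the difference mode is g*(1/V1 + 1/V2)
  n <- 2
  a_cm <- p$tt_radius * 1e-4
  len <- (p$v_tt * 1e-9) / (pi * a_cm^2)
  dr <- a_cm / n
  g <- p$d_rad_ca * 2 * pi * (a_cm / 2) * len / dr * 1e6
  vsh <- p$v_tt * c(3, 1) / 4
  lambda <- g * (1 / vsh[1] + 1 / vsh[2])
  prof <- c(2.2, 1.8)
  d <- radial_diffusion_rhs(prof, p, "ca")
  # d(difference)/dt = -lambda * difference
  expect_equal(d[1] - d[2], -lambda * (prof[1] - prof[2]), tolerance = 1e-10)
})

test_that("compartment exchange follows its definition and decays exponentially", {
  expect_equal(compartment_exchange(2, 2, 1.5, 100), 0)
  # doubling tau halves the flux at fixed gradient
  expect_equal(compartment_exchange(3, 1, 2, 200),
               2 * compartment_exchange(3, 1, 2, 400))
  expect_error(compartment_exchange(1, 2, 1, 0), "tau")
  # an isolated pair against an infinite reservoir decays with tau exactly
  tau <- 740; v <- 2.5; c0 <- 3; cb <- 2
  dt <- 0.5; c <- c0
  for (i in seq_len(2000)) c <- c - dt * compartment_exchange(c, cb, v, tau) / v
  t_end <- 2000 * dt
  expect_equal(c, cb + (c0 - cb) * exp(-t_end / tau), tolerance = 1e-3)
})

test_that("the volume-weighted mean lies between shell extremes", {
  p <- default_parameters()
  expect_equal(mean_tubular_concentration(rep(1.7, 9), params = p), 1.7)
  expect_equal(mean_tubular_concentration(c(1, 3), volumes = c(2, 2)), 2)
  set.seed(7)
  prof <- runif(9, 0.1, 5)
  vols <- runif(9, 0.5, 2)
  m <- mean_tubular_concentration(prof, volumes = vols)
  expect_equal(m, sum(prof * vols) / sum(vols))
  expect_gte(m, min(prof)); expect_lte(m, max(prof))
  expect_error(mean_tubular_concentration(1:3, volumes = 1:2), "length")
})

test_that("shell depletion is ordered outward during the L-type Ca2+ current", {
  tr <- last_cycle_trace(fx_paced())
  ical <- tr$i_cal_s + tr$i_cal_t
  # during the strong inward phase, the membrane-adjacent shell is the most
  # depleted and depletion decreases monotonically toward the core
  sel <- which(ical < 0.5 * min(ical))
  prof <- as.matrix(tr[sel, paste0("ca_t", 1:9)])
  expect_true(all(diff(t(prof)) >= -1e-12))
})

test_that("cleft oscillations are smaller than first-shell oscillations", {
  tr <- last_cycle_trace(fx_paced())
  expect_lt(max(tr$ca_c) - min(tr$ca_c), max(tr$ca_t1) - min(tr$ca_t1))
  expect_lt(max(tr$k_c) - min(tr$k_c), max(tr$k_t1) - min(tr$k_t1))
})

test_that("with membrane transport silenced every compartment relaxes to bulk", {
  p <- default_parameters()
  for (nm in c("g_na", "g_naps", "p_cal", "g_kto", "g_kr", "g_ks", "g_k1",
               "g_bna", "g_bca", "g_kna", "p_nsca", "k_naca", "i_nak_max",
               "g_pca", "stim_amp"))
    p[[nm]] <- 0
  y <- fx_rest()
  set.seed(11)
  y[paste0("ca_t", 1:9)] <- runif(9, 1.2, 2.8)
  y["ca_c"] <- 1.5
  pv <- ttmyo:::param_vector(p)
  dev <- function(y) max(abs(c(y[paste0("ca_t", 1:9)], y[["ca_c"]]) - p$ca_b))
  devs <- numeric(10)
  for (i in 1:10) {
    y <- ttmyo:::.integrate_span(y, 0, 10000, pv)$y_end
    devs[i] <- dev(y)
  }
  expect_true(all(diff(devs) < 0))        # monotone decay in max-norm
  expect_lt(devs[10], 0.05)               # approaching bulk
})
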