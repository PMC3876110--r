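test_that("basic-model defaults carry the documented transporter settings", {
  p <- default_parameters()
  expect_equal(p$f_cal_t, 0.64)
  expect_equal(p$f_naca_t, 0.56)
  expect_equal(p$f_pca_t, 0.2)
  expect_equal(p$tau_ca_ct, 240)
  expect_equal(p$area_frac_t, 0.56)
  expect_true(all(c("v_tt", "tau_k_ct") %in% attr(p, "calibrated")))
  expect_silent(validate_parameters(p))
})

test_that("shell geometry partitions the cylinder exactly", {
  g <- shell_geometry(0.45, 1200, 9)
  expect_equal(nrow(g), 9)
  # conservation of volume to near machine precision
  expect_equal(sum(g$volume), pi * 0.45^2 * 1200, tolerance = 1e-12)
  # equal-thickness annuli: volume of shell k proportional to r_k^2 - r_{k-1}^2
  k <- 9:1  # shell 1 is outermost
  expect_equal(g$volume / g$volume[9], (k^2 - (k - 1)^2), tolerance = 1e-12)
  # shell 1 touches the membrane, last shell is the axis core
  expect_equal(g$r_outer[1], 0.45)
  expect_equal(g$r_inner[9], 0)
  # degenerate partition
  g1 <- shell_geometry(0.2, 10, 1)
  expect_equal(g1$volume, pi * 0.2^2 * 10)
  expect_error(shell_geometry(-1, 10), "radius")
  expect_error(shell_geometry(0.2, 0), "length")
})

test_that("shell volumes used by the model sum to the configured lumen volume", {
  p <- default_parameters()
  v <- shell_volumes(p)
  expect_length(v, 9)
  expect_equal(sum(v), p$v_tt, tolerance = 1e-12)
  expect_true(all(v > 0))
})

test_that("out-of-domain parameters are rejected at validation with key names", {
  expect_error(validate_parameters(default_parameters(f_cal_t = 1.2)), "f_cal_t")
  expect_error(validate_parameters(default_parameters(tau_ca_ct = -5)), "tau_ca_ct")
  p <- unclass(default_parameters())
  p$g_na <- NULL
  expect_error(validate_parameters(structure(p, class = "ttmyo_params")), "g_na")
  p2 <- unclass(default_parameters())
  p2$bogus <- 1
  expect_error(validate_parameters(structure(p2, class = "ttmyo_params")), "bogus")
  expect_error(default_parameters(not_a_param = 1), "not_a_param")
})

test_that("the flattened parameter vector matches the compiled layout", {
  pv <- ttmyo:::param_vector(default_parameters())
  expect_equal(names(pv), .Call("c_param_names", PACKAGE = "ttmyo"))
  expect_false(any(is.na(pv)))
})
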