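test_that("pacing bookkeeping delivers the requested number of stimuli", {
  p <- default_parameters()
  sim <- pace_to_steady_state(1, p, duration_s = 12, record = NULL,
                              periodicity_tol = Inf, cache = FALSE,
                              start = fx_rest())
  expect_equal(nrow(sim$cycles), 12)
  expect_equal(unique(sim$cycles$freq), 1)
  expect_equal(tail(sim$cycles$t_end, 1), 12)
  expect_true(is.finite(sim$periodicity))
})

test_that("a frequency step onto the same frequency is a no-perturbation", {
  p <- default_parameters()
  base <- pace_to_steady_state(1, p, duration_s = 60, record = NULL,
                               periodicity_tol = Inf, cache = FALSE,
                               start = fx_rest())
  cont <- frequency_step(1, 1, 10, p, steady = base)
  # per-cycle summaries stay as periodic as the base run was
  drift <- abs(diff(cont$cycles$cai_area)) / cont$cycles$cai_area[-1]
  expect_lt(max(drift), 5e-3)
})

test_that("a zero-duration train equals continued base-rate pacing", {
  p <- default_parameters()
  base <- pace_to_steady_state(1, p, duration_s = 40, record = NULL,
                               periodicity_tol = Inf, cache = FALSE,
                               start = fx_rest())
  out <- train_protocol(1, 3, durations_s = 0, params = p, post_s = 10,
                        steady = base)
  expect_named(out, "train_0s")
  expect_equal(unique(out$train_0s$cycles$freq), 1)
  expect_equal(nrow(out$train_0s$cycles), 10)
})

test_that("protocols are restart-safe at segment boundaries", {
  p <- default_parameters()
  y <- fx_rest()
  whole <- simulate_model(y, p, pacing_protocol(c(1, 4), c(2, 3)))
  first <- simulate_model(y, p, pacing_protocol(c(1, 4)))
  second <- simulate_model(first$final_state, p, pacing_protocol(c(2, 3)))
  keep <- setdiff(state_layout()$names, state_layout()$accumulators)
  expect_equal(second$final_state[keep], whole$final_state[keep],
               tolerance = 1e-6)
})

test_that("the steady-state cache returns the identical object", {
  p <- default_parameters()
  s1 <- pace_to_steady_state(1, p, duration_s = 6, record = NULL,
                             periodicity_tol = Inf, start = fx_rest())
  s2 <- pace_to_steady_state(1, p, duration_s = 6, record = NULL,
                             periodicity_tol = Inf, start = fx_rest())
  expect_identical(s1$cycles, s2$cycles)
})

test_that("dialysed AP validation reports APD50 <= APD90 at each rate", {
  tab <- ap_validation(freqs = c(1, 2), n_pulses = 4)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(tab$apd50)))
  expect_true(all(tab$apd50 <= tab$apd90))
  expect_true(all(tab$apd90 > 100 & tab$apd90 < 500))
})
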