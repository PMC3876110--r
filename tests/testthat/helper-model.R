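# Shared fixtures, computed once per test run and memoized.

.fx <- new.env(parent = emptyenv())

fx_params <- function(...) default_parameters(...)

fx_rest <- function() {
  if (is.null(.fx$rest)) .fx$rest <- initial_state(fx_params())
  .fx$rest
}

# a short paced run (10 cycles at 1 Hz) with a dense trace of the last
# two cycles; enough for per-cycle metric and invariant checks
fx_paced <- function() {
  if (is.null(.fx$paced)) {
    .fx$paced <- simulate_model(fx_rest(), fx_params(),
                                pacing_protocol(c(1, 10)),
                                record = c(9, 10), sample_ms = 1)
  }
  .fx$paced
}

last_cycle_trace <- function(sim) {
  dplyr::filter(sim$trace, .data$cycle == max(.data$cycle))
}
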