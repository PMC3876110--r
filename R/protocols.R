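# Reusable stimulation protocols: steady-state pacing, frequency steps,
# high-frequency trains, and the AP-validation runs.

# in-memory steady-state cache keyed by (parameter hash, freq, clamp mode,
# duration, tolerance); optional on-disk mirror under options(ttmyo.cache_dir)
.ss_cache <- new.env(parent = emptyenv())

.cache_key <- function(params, freq, clamp, duration_s, rtol) {
  rlang::hash(list(param_vector(params), freq, clamp$mode, duration_s, rtol))
}

#' Determine the diastolic stimulus threshold
#'
#' Bisects the amplitude of the rectangular stimulus pulse (duration
#' `params$stim_dur`) until the smallest amplitude that elicits an action
#' potential (overshoot above 0 mV within 100 ms) from the quiescent state
#' is bracketed to `precision`.
#'
#' @param params a `ttmyo_params` object.
#' @param state starting state; defaults to [initial_state()].
#' @param precision relative bracket width for the bisection.
#' @return threshold amplitude (pA, negative).
#' @export
find_stim_threshold <- function(params, state = NULL, precision = 0.02) {
  params <- validate_parameters(params)
  if (is.null(state)) state <- initial_state(params)
  pvec <- param_vector(params)
  fires <- function(amp) {
    pv <- pvec; pv["stim_amp"] <- amp
    sp1 <- .integrate_span(state, 0, params$stim_dur, pv)
    pv["stim_amp"] <- 0
    sp2 <- .integrate_span(sp1$y_end, params$stim_dur, 100, pv,
                           times = seq(params$stim_dur, 100, by = 1))
    max(sp2$table[, "v"]) > 0
  }
  lo <- -100  # certainly subthreshold
  hi <- -20000
  if (!fires(hi)) abort("no AP even at -20 nA; check parameters")
  while (abs(hi - lo) > precision * abs(hi)) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Pace to steady state at a fixed frequency
#'
#' Stimulates the model at `freq` for `duration_s` (1200 s by default) and
#' performs a periodicity audit: the relative componentwise difference of
#' the last two cycle-start states must be below `periodicity_tol`;
#' otherwise a warning is attached (and raised). Results are cached in
#' memory (and optionally on disk) keyed by parameter hash, frequency,
#' clamp mode and duration.
#'
#' @param freq stimulation frequency (Hz), > 0.
#' @param params a `ttmyo_params` object.
#' @param clamp a [clamp_config()].
#' @param duration_s pacing duration (s).
#' @param record passed to [simulate_model()] (default: dense trace of the
#'   last cycle).
#' @param periodicity_tol relative tolerance of the steady-state audit.
#' @param rtol solver tolerance.
#' @param cache use the steady-state cache.
#' @param start initial state; defaults to [initial_state()].
#' @return a `ttmyo_sim` with an added `periodicity` element (max relative
#'   componentwise change over the final cycle).
#' @export
pace_to_steady_state <- function(freq, params, clamp = clamp_config("free"),
                                 duration_s = 1200, record = "last",
                                 periodicity_tol = 1e-3, rtol = 1e-6,
                                 cache = TRUE, start = NULL) {
  if (freq <= 0) abort("freq must be > 0")
  params <- validate_parameters(params)
  key <- .cache_key(params, freq, clamp, duration_s, rtol)
  if (cache && !is.null(.ss_cache[[key]])) return(.ss_cache[[key]])
  cache_dir <- getOption("ttmyo.cache_dir", NULL)
  if (cache && !is.null(cache_dir)) {
    f <- file.path(cache_dir, paste0("ss-", key, ".rds"))
    if (file.exists(f)) {
      sim <- readRDS(f)
      .ss_cache[[key]] <- sim
      return(sim)
    }
  }
  if (is.null(start)) start <- initial_state(params)
  n_cycles <- round(freq * duration_s)
  pr <- pacing_protocol(c(freq, duration_s), clamp = clamp)
  rec <- if (identical(record, "last")) n_cycles else record
  sim <- simulate_model(start, params, pr, record = rec, rtol = rtol)
  # periodicity audit on the last two end-diastolic states
  last2 <- tail(sim$cycles, 2)
  comp <- c("v_end", "ca_i_end", "na_i_end", "k_i_end", "ca_nsr_end",
            "ca_c_end", "k_c_end", "ca_t1_end")
  dev <- max(abs(unlist(last2[2, comp]) - unlist(last2[1, comp])) /
               pmax(abs(unlist(last2[1, comp])), 1e-8))
  sim$periodicity <- dev
  if (dev > periodicity_tol)
    warn(sprintf("periodicity audit: max relative cycle-to-cycle change %.3g > %g",
                 dev, periodicity_tol))
  if (cache) {
    .ss_cache[[key]] <- sim
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(sim, file.path(cache_dir, paste0("ss-", key, ".rds")))
    }
  }
  sim
}

#' Sudden change of stimulation frequency
#'
#' From the steady state at `f1`, steps the stimulation frequency to `f2`
#' and records per-cycle summaries for `observe_s`.
#'
#' @param f1,f2 frequencies (Hz) before and after the step.
#' @param observe_s observation time after the step (s).
#' @param params a `ttmyo_params` object.
#' @param clamp a [clamp_config()] applied during both phases.
#' @param record cycles (indices within the post-step run) to keep as
#'   dense traces.
#' @param steady optional precomputed steady-state `ttmyo_sim` at `f1`.
#' @param steady_duration_s pacing time used to establish the `f1` steady
#'   state when it is not supplied.
#' @param rtol solver tolerance.
#' @return a `ttmyo_sim` covering the post-step period.
#' @export
frequency_step <- function(f1, f2, observe_s, params,
                           clamp = clamp_config("free"), record = NULL,
                           steady = NULL, steady_duration_s = 1200,
                           rtol = 1e-6) {
  params <- validate_parameters(params)
  if (is.null(steady))
    steady <- pace_to_steady_state(f1, params, clamp,
                                   duration_s = steady_duration_s, rtol = rtol)
  pr <- pacing_protocol(c(f2, observe_s), clamp = clamp)
  simulate_model(steady$final_state, params, pr, record = record, rtol = rtol)
}

#' High-frequency stimulation train with return to the base rate
#'
#' From the steady state at `base_f`, applies a train at `train_f` for each
#' requested duration, followed by `post_s` of renewed pacing at `base_f`
#' (set `post_s = 0` to omit).
#'
#' @param base_f base frequency (Hz).
#' @param train_f train frequency (Hz).
#' @param durations_s numeric vector of train durations (s); 0 means
#'   continued base pacing.
#' @param params a `ttmyo_params` object.
#' @param post_s duration of the return-to-base segment (s).
#' @param clamp a [clamp_config()].
#' @param steady optional precomputed base steady state.
#' @param steady_duration_s pacing time for the base steady state.
#' @param rtol solver tolerance.
#' @return named list of `ttmyo_sim`, one per duration.
#' @export
train_protocol <- function(base_f = 1, train_f = 3, durations_s = 700,
                           params = default_parameters(), post_s = 700,
                           clamp = clamp_config("free"), steady = NULL,
                           steady_duration_s = 1200, rtol = 1e-6) {
  if (!length(durations_s)) abort("durations_s must be non-empty")
  params <- validate_parameters(params)
  if (is.null(steady))
    steady <- pace_to_steady_state(base_f, params, clamp,
                                   duration_s = steady_duration_s, rtol = rtol)
  out <- lapply(durations_s, function(d) {
    segs <- list()
    if (d > 0) segs <- c(segs, list(c(train_f, d)))
    if (post_s > 0) segs <- c(segs, list(c(base_f, post_s)))
    if (!length(segs)) abort("empty train protocol")
    pr <- do.call(pacing_protocol, c(segs, list(clamp = clamp)))
    simulate_model(steady$final_state, params, pr, rtol = rtol)
  })
  setNames(out, paste0("train_", durations_s, "s"))
}

#' Frequency dependence of the AP with dialysed intracellular Na+/K+
#'
#' Applies a fixed number of stimulation pulses at each frequency with
#' intracellular Na+ and K+ held at pipette values (10 and 130 mM), then
#' measures APD50 and APD90 on the last AP.
#'
#' @param freqs stimulation frequencies (Hz).
#' @param params a `ttmyo_params` object.
#' @param n_pulses pulses per frequency.
#' @param na_i,k_i pipette concentrations (mM).
#' @param rtol solver tolerance.
#' @return tibble with `freq`, `apd50`, `apd90` (ms).
#' @export
ap_validation <- function(freqs = c(0.5, 1, 2), params = default_parameters(),
                          n_pulses = 15, na_i = 10, k_i = 130, rtol = 1e-6) {
  params <- validate_parameters(params)
  clamp <- clamp_config("fix_intracellular_NaK", na_i = na_i, k_i = k_i)
  y0 <- initial_state(params)
  purrr::map_dfr(freqs, function(f) {
    pr <- pacing_protocol(c(f, n_pulses / f), clamp = clamp)
    sim <- simulate_model(y0, params, pr, record = n_pulses, sample_ms = 0.5,
                          rtol = rtol)
    tr <- dplyr::filter(sim$trace, .data$cycle == max(.data$cycle))
    tibble(freq = f,
           apd50 = apd(tr, 0.5),
           apd90 = apd(tr, 0.9))
  })
}

#' Frequency dependence of diastolic intracellular Ca2+ and Na+
#'
#' Runs a fixed number of APs at each frequency from the quiescent state
#' and reports the end-diastolic `[Ca2+]`i (after `n_ap_ca` pulses) and
#' `[Na+]`i (after `n_ap_na` pulses), normalized to the 1 Hz values.
#'
#' @param freqs stimulation frequencies (Hz); must include 1.
#' @param params a `ttmyo_params` object.
#' @param n_ap_ca,n_ap_na number of APs used for the Ca2+ and Na+ readouts.
#' @param rtol solver tolerance.
#' @return tibble with `freq`, `ca_i_end`, `na_i_end` and the normalized
#'   columns `ca_i_rel`, `na_i_rel`.
#' @export
freq_dependence <- function(freqs = c(0.25, 0.5, 1, 1.5, 2, 2.5, 3),
                            params = default_parameters(),
                            n_ap_ca = 100, n_ap_na = 600, rtol = 1e-6) {
  params <- validate_parameters(params)
  stopifnot(1 %in% freqs)
  y0 <- initial_state(params)
  res <- purrr::map_dfr(freqs, function(f) {
    n <- max(n_ap_ca, n_ap_na)
    pr <- pacing_protocol(c(f, n / f))
    sim <- simulate_model(y0, params, pr, rtol = rtol)
    tibble(freq = f,
           ca_i_end = sim$cycles$ca_i_end[n_ap_ca],
           na_i_end = sim$cycles$na_i_end[n_ap_na])
  })
  res$ca_i_rel <- res$ca_i_end / res$ca_i_end[res$freq == 1]
  res$na_i_rel <- res$na_i_end / res$na_i_end[res$freq == 1]
  res
}

#' Steady-state Ca2+-transient sensitivity to t-tubular transporter fractions
#'
#' For a grid of t-tubular fractions of the Na+/Ca2+ exchanger and of the
#' sarcolemmal Ca2+ pump (at a fixed t-tubular fraction of L-type Ca2+
#' channels), computes the percentage change of the whole-cycle cytosolic
#' Ca2+-transient integral relative to the matched simulation with all
#' extracellular concentrations fixed at bulk values.
#'
#' @param f_cal_t t-tubular fraction of L-type Ca2+ channels.
#' @param f_naca_t,f_pca_t grids of t-tubular fractions.
#' @param freq stimulation frequency (Hz).
#' @param params base parameter set.
#' @param duration_s pacing time per grid point (s).
#' @param rtol solver tolerance.
#' @return tibble with `f_cal_t`, `f_naca_t`, `f_pca_t` and
#'   `d_cai_area_rel` (%, negative = reduction).
#' @export
sweep_fractions <- function(f_cal_t = 0.64,
                            f_naca_t = c(0.2, 0.56, 0.9),
                            f_pca_t = c(0.0, 0.2, 0.6, 0.9),
                            freq = 1, params = default_parameters(),
                            duration_s = 400, rtol = 1e-6) {
  params <- validate_parameters(params)
  y0 <- initial_state(params)
  grid <- tidyr::expand_grid(f_cal_t = f_cal_t, f_naca_t = f_naca_t,
                             f_pca_t = f_pca_t)
  purrr::pmap_dfr(grid, function(f_cal_t, f_naca_t, f_pca_t) {
    p <- params
    p$f_cal_t <- f_cal_t; p$f_naca_t <- f_naca_t; p$f_pca_t <- f_pca_t
    free <- simulate_model(y0, p, pacing_protocol(c(freq, duration_s)),
                           rtol = rtol)
    ref <- simulate_model(y0, p,
                          pacing_protocol(c(freq, duration_s),
                                          clamp = clamp_config("clamp_all_extracellular")),
                          rtol = rtol)
    tibble(f_cal_t = f_cal_t, f_naca_t = f_naca_t, f_pca_t = f_pca_t,
           d_cai_area_rel = transient_area_change(free, ref))
  })
}
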