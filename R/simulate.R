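# Assembled right-hand side, stiff integration and the simulation engine.

.aux_n <- local({
  n <- NULL
  function() {
    if (is.null(n)) n <<- length(.Call("c_aux_names", PACKAGE = "ttmyo"))
    n
  }
})

# single evaluation of the compiled right-hand side (diagnostics/tests)
.rhs_eval <- function(t, y, pvec) {
  .Call("c_eval", as.numeric(t), as.numeric(y), as.numeric(pvec),
        PACKAGE = "ttmyo")
}

#' Evaluate the assembled model right-hand side
#'
#' Computes the time derivative of the full state vector together with all
#' per-pool membrane currents and SR fluxes. The tubular membrane pool sees
#' the concentrations of the first (membrane-adjacent) t-tubular shell; the
#' surface pool sees the cleft concentrations. Clamped compartments (per
#' `clamp`) return identically zero derivatives.
#'
#' @param state named state vector (see [state_layout()]).
#' @param params a `ttmyo_params` object.
#' @param clamp a clamp configuration from [clamp_config()].
#' @param stim_amp stimulus current (pA, negative = depolarizing) applied
#'   at this instant.
#' @param t time (ms); the autonomous model ignores it.
#' @return list with `derivatives` (named, per ms) and `aux` (named
#'   currents in pA and SR fluxes in fmol/ms).
#' @examples
#' p <- default_parameters()
#' y <- initial_state(p, tol = 1e-6)
#' rhs <- assemble_rhs(y, p)
#' rhs$aux[["i_tot"]]
#' @export
assemble_rhs <- function(state, params, clamp = clamp_config("free"),
                         stim_amp = 0, t = 0) {
  params <- validate_parameters(params)
  if (any(state[c("ca_i", "ca_d", "ca_nsr", "ca_jsr", "na_i", "k_i")] <= 0) ||
      any(state[state_layout()$tubular] <= 0) ||
      any(state[state_layout()$cleft] <= 0))
    abort("invalid state: non-positive concentration")
  pvec <- .apply_clamp(param_vector(params), clamp)
  pvec["stim_amp"] <- stim_amp
  out <- .rhs_eval(t, state, pvec)
  bad <- !is.finite(out$derivatives)
  if (any(bad))
    abort(paste0("non-finite derivative for state component(s): ",
                 paste(names(out$derivatives)[bad], collapse = ", ")))
  out
}

#' Clamp configuration
#'
#' Selects which concentration pools are held fixed (zero derivative):
#' `"free"` (all dynamic), `"clamp_cleft"` (cleft concentrations fixed),
#' `"clamp_all_extracellular"` (cleft and all nine t-tubular shells fixed),
#' or `"fix_intracellular_NaK"` (intracellular Na+ and K+ fixed, as in
#' pipette-dialysed validation recordings).
#'
#' @param mode one of the four modes above.
#' @param na_i,k_i override values (mM) applied when intracellular Na+/K+
#'   are fixed.
#' @return a `ttmyo_clamp` list.
#' @export
clamp_config <- function(mode = c("free", "clamp_cleft",
                                  "clamp_all_extracellular",
                                  "fix_intracellular_NaK"),
                         na_i = 10, k_i = 130) {
  mode <- match.arg(mode)
  structure(list(mode = mode, na_i = na_i, k_i = k_i),
            class = "ttmyo_clamp")
}

.apply_clamp <- function(pvec, clamp) {
  stopifnot(inherits(clamp, "ttmyo_clamp"))
  pvec["clamp_tub"] <- as.numeric(clamp$mode == "clamp_all_extracellular")
  pvec["clamp_cleft"] <- as.numeric(clamp$mode %in%
                                      c("clamp_cleft", "clamp_all_extracellular"))
  pvec["fix_naki"] <- as.numeric(clamp$mode == "fix_intracellular_NaK")
  pvec
}

# clamped-at-bulk modes pin the extracellular compartments to bulk values;
# the fixed-NaK validation mode dialyses the cell
.apply_clamp_state <- function(y, pvec, clamp) {
  if (clamp$mode == "clamp_all_extracellular") {
    y[paste0("ca_t", 1:9)] <- pvec["ca_b"]
    y[paste0("k_t", 1:9)] <- pvec["k_b"]
    y[paste0("na_t", 1:9)] <- pvec["na_b"]
  }
  if (clamp$mode %in% c("clamp_cleft", "clamp_all_extracellular")) {
    y["ca_c"] <- pvec["ca_b"]; y["k_c"] <- pvec["k_b"]; y["na_c"] <- pvec["na_b"]
  }
  if (clamp$mode == "fix_intracellular_NaK") {
    y["na_i"] <- clamp$na_i
    y["k_i"] <- clamp$k_i
  }
  y
}

# per-state absolute tolerances scaled to each block's magnitude
.atol_vector <- function(lay, scale = 1) {
  atol <- setNames(rep(1e-8, lay$n_state), lay$names)
  atol["v"] <- 1e-6
  atol[c("ca_i", "ca_d")] <- 1e-11
  atol[c("ca_nsr", "ca_jsr")] <- 1e-8
  atol[c("na_i", "k_i")] <- 1e-6
  atol[grep("^ca_t", lay$names)] <- 1e-9
  atol["ca_c"] <- 1e-9
  atol[lay$accumulators] <- 1e-2
  atol * scale
}

# integrate [t0, t1] with constant stimulus; optional dense sampling
.integrate_span <- function(y, t0, t1, pvec, times = NULL,
                            rtol = 1e-6, atol = NULL, with_aux = FALSE) {
  lay <- state_layout()
  if (is.null(atol)) atol <- .atol_vector(lay)
  tt <- if (is.null(times)) c(t0, t1) else unique(c(t0, times, t1))
  nout <- if (with_aux) .aux_n() else 1
  onames <- if (with_aux) aux_names() else "dummy"
  solve1 <- function(method) {
    suppressWarnings(deSolve::ode(
      y = y, times = tt, parms = pvec,
      func = "c_derivs", dllname = "ttmyo", initfunc = "c_initmod",
      nout = nout, outnames = onames,
      method = method, rtol = rtol, atol = atol, maxsteps = 50000,
      hini = 1e-3
    ))
  }
  out <- tryCatch(solve1("lsoda"), error = function(e) NULL)
  # lsoda occasionally stalls on near-equilibrium states; vode is the backup
  if (is.null(out) || attr(out, "istate")[1] < 0)
    out <- tryCatch(solve1("vode"), error = function(e) out)
  if (is.null(out))
    abort("stiff integration failed at the first step")
  if (attr(out, "istate")[1] < 0)
    abort(sprintf("stiff integration failed near t = %.3f ms (last valid state returned)",
                  max(out[, 1])))
  y_end <- out[nrow(out), 1 + seq_len(lay$n_state)]
  if (any(!is.finite(y_end)))
    abort(paste0("non-finite state after integration: ",
                 paste(lay$names[!is.finite(y_end)], collapse = ", ")))
  list(table = out, y_end = setNames(as.numeric(y_end), lay$names))
}

#' Pacing protocol definition
#'
#' An ordered list of constant-frequency segments (frequency 0 = rest),
#' executed left to right. The stimulus is a rectangular current pulse of
#' `stim_dur` ms at the amplitude stored in the parameter set (or
#' overridden here).
#'
#' @param ... numeric pairs given as `c(freq_hz, duration_s)` or a single
#'   data frame with columns `freq` and `duration_s`.
#' @param clamp a [clamp_config()].
#' @param stim_amp optional stimulus amplitude override (pA, negative).
#' @return a `ttmyo_protocol` object.
#' @examples
#' pr <- pacing_protocol(c(1, 5), c(2.5, 5))  # 5 s at 1 Hz then 5 s at 2.5 Hz
#' @export
pacing_protocol <- function(..., clamp = clamp_config("free"), stim_amp = NULL) {
  segs <- list(...)
  if (length(segs) == 1 && is.data.frame(segs[[1]])) {
    df <- as_tibble(segs[[1]])
  } else {
    df <- tibble(
      freq = vapply(segs, `[`, numeric(1), 1),
      duration_s = vapply(segs, `[`, numeric(1), 2)
    )
  }
  if (!all(c("freq", "duration_s") %in% names(df)))
    abort("protocol needs `freq` and `duration_s`")
  if (any(df$duration_s <= 0)) abort("segment durations must be > 0")
  if (any(df$freq < 0)) abort("frequencies must be >= 0")
  structure(list(segments = df, clamp = clamp, stim_amp = stim_amp),
            class = "ttmyo_protocol")
}

#' Run the model under a pacing protocol
#'
#' Integrates the stiff ODE system cycle by cycle. For every stimulated
#' cycle the per-cycle integrals of the Ca2+-carrying currents and of the
#' cytosolic Ca2+ concentration are accumulated inside the solver (extra
#' quadrature states), and the end-diastolic state (the sample immediately
#' before the next stimulus) is recorded. Rest segments are integrated in
#' chunks with the same bookkeeping.
#'
#' @param state initial named state vector.
#' @param params a `ttmyo_params` object.
#' @param protocol a [pacing_protocol()].
#' @param record which cycles to keep as a dense trace: `NULL` (none),
#'   `"last"` (last cycle of each segment), `"all"`, or an integer vector
#'   of global cycle indices.
#' @param sample_ms trace sampling interval (ms).
#' @param rtol relative solver tolerance.
#' @param atol_scale multiplier on the per-state absolute tolerances.
#' @return a `ttmyo_sim` object: `cycles` (per-cycle tibble with
#'   end-diastolic values and cycle integrals), `trace` (tibble or `NULL`),
#'   `final_state`, `protocol`, `solver`, `layout` and `params_hash`.
#' @export
simulate_model <- function(state, params, protocol,
                           record = NULL, sample_ms = 1,
                           rtol = 1e-6, atol_scale = 1) {
  params <- validate_parameters(params)
  stopifnot(inherits(protocol, "ttmyo_protocol"))
  lay <- state_layout()
  pvec0 <- .apply_clamp(param_vector(params), protocol$clamp)
  stim_amp <- protocol$stim_amp %||% params$stim_amp
  stim_dur <- params$stim_dur
  atol <- .atol_vector(lay, atol_scale)
  y <- .apply_clamp_state(state, pvec0, protocol$clamp)
  acc <- lay$accumulators

  # global cycle numbering across segments
  n_cyc_seg <- ifelse(protocol$segments$freq > 0,
                      round(protocol$segments$freq * protocol$segments$duration_s),
                      ceiling(protocol$segments$duration_s / 10))
  total_cycles <- sum(n_cyc_seg)
  rec_idx <- if (is.null(record)) integer(0)
  else if (identical(record, "all")) seq_len(total_cycles)
  else if (identical(record, "last")) cumsum(n_cyc_seg)
  else as.integer(record)

  vsh <- shell_volumes(params)
  cyc_mat <- matrix(NA_real_, nrow = total_cycles, ncol = length(.cycle_cols))
  colnames(cyc_mat) <- .cycle_cols
  traces <- list()
  t_abs <- 0
  cycle <- 0L

  for (seg in seq_len(nrow(protocol$segments))) {
    freq <- protocol$segments$freq[seg]
    n_cyc <- n_cyc_seg[seg]
    period <- if (freq > 0) 1000 / freq else 10000
    for (k in seq_len(n_cyc)) {
      cycle <- cycle + 1L
      y[acc] <- 0
      rec <- cycle %in% rec_idx
      tr <- NULL
      if (freq > 0) {
        pvec <- pvec0; pvec["stim_amp"] <- stim_amp
        sp1 <- .integrate_span(y, 0, stim_dur, pvec,
                               times = if (rec) seq(0, stim_dur, by = min(sample_ms, stim_dur)),
                               rtol = rtol, atol = atol, with_aux = rec)
        pvec["stim_amp"] <- 0
        sp2 <- .integrate_span(sp1$y_end, stim_dur, period, pvec,
                               times = if (rec) seq(stim_dur, period, by = sample_ms),
                               rtol = rtol, atol = atol, with_aux = rec)
        if (rec) tr <- rbind(sp1$table[-nrow(sp1$table), , drop = FALSE], sp2$table)
        y_new <- sp2$y_end
      } else {
        pvec <- pvec0; pvec["stim_amp"] <- 0
        sp <- .integrate_span(y, 0, period, pvec,
                              times = if (rec) seq(0, period, by = sample_ms),
                              rtol = rtol, atol = atol, with_aux = rec)
        if (rec) tr <- sp$table
        y_new <- sp$y_end
      }
      if (!is.null(tr)) {
        tr <- as_tibble(as.data.frame(tr))
        tr$time <- tr$time + t_abs
        tr$cycle <- cycle
        traces[[length(traces) + 1]] <- tr
      }
      cyc_mat[cycle, ] <- .cycle_summary(y_new, cycle, seg, freq, t_abs, period, vsh)
      y <- y_new
      t_abs <- t_abs + period
    }
  }

  cycles <- as_tibble(as.data.frame(cyc_mat))
  structure(list(
    cycles = cycles,
    trace = if (length(traces)) dplyr::bind_rows(traces) else NULL,
    final_state = y,
    protocol = protocol,
    params = params,
    params_hash = rlang::hash(param_vector(params)),
    solver = list(method = "lsoda", rtol = rtol, atol_scale = atol_scale),
    layout = lay
  ), class = "ttmyo_sim")
}

# amol of Ca2+ per pA*ms of Ca2+-carried charge (divalent)
.AMOL_PER_PAMS_CA <- 1e3 / (2 * 96485)
.AMOL_PER_PAMS <- 1e3 / 96485

.cycle_cols <- c(
  "cycle", "segment", "freq", "t_start", "t_end", "v_end",
  "ca_i_end", "na_i_end", "k_i_end", "ca_nsr_end", "ca_jsr_end",
  "ca_c_end", "k_c_end", "na_c_end", "ca_t1_end", "k_t1_end", "na_t1_end",
  "ca_t_mean_end", "k_t_mean_end", "cai_area",
  "int_ical_s", "int_ical_t", "int_inaca_s", "int_inaca_t",
  "int_inaca_pos_s", "int_inaca_pos_t", "int_icab_s", "int_icab_t",
  "int_ipca_s", "int_ipca_t", "n_ca_net_s", "n_ca_net_t", "ca_entry"
)

.cycle_summary <- function(y, cycle, segment, freq, t_start, period, vsh) {
  n_ca_net_s <- (y[["int_ical_s"]] - 2 * y[["int_inaca_s"]] +
                   y[["int_icab_s"]] + y[["int_ipca_s"]]) * .AMOL_PER_PAMS_CA
  n_ca_net_t <- (y[["int_ical_t"]] - 2 * y[["int_inaca_t"]] +
                   y[["int_icab_t"]] + y[["int_ipca_t"]]) * .AMOL_PER_PAMS_CA
  ca_entry <- -(y[["int_ical_s"]] + y[["int_ical_t"]]) * .AMOL_PER_PAMS_CA +
    (y[["int_inaca_pos_s"]] + y[["int_inaca_pos_t"]]) * .AMOL_PER_PAMS
  c(cycle, segment, freq, t_start / 1000, (t_start + period) / 1000,
    y[["v"]], y[["ca_i"]], y[["na_i"]], y[["k_i"]],
    y[["ca_nsr"]], y[["ca_jsr"]],
    y[["ca_c"]], y[["k_c"]], y[["na_c"]],
    y[["ca_t1"]], y[["k_t1"]], y[["na_t1"]],
    sum(y[paste0("ca_t", 1:9)] * vsh) / sum(vsh),
    sum(y[paste0("k_t", 1:9)] * vsh) / sum(vsh),
    y[["int_ca_i"]],
    y[["int_ical_s"]], y[["int_ical_t"]],
    y[["int_inaca_s"]], y[["int_inaca_t"]],
    y[["int_inaca_pos_s"]], y[["int_inaca_pos_t"]],
    y[["int_icab_s"]], y[["int_icab_t"]],
    y[["int_ipca_s"]], y[["int_ipca_t"]],
    n_ca_net_s, n_ca_net_t, ca_entry)
}

#' @export
print.ttmyo_sim <- function(x, ...) {
  cat("<ttmyo_sim>\n")
  cat(sprintf("  %d cycles, %.1f s simulated; trace: %s\n",
              nrow(x$cycles), max(x$cycles$t_end),
              if (is.null(x$trace)) "none" else
                sprintf("%d samples over %d cycles", nrow(x$trace),
                        length(unique(x$trace$cycle)))))
  cat(sprintf("  final end-diastolic: Vm %.1f mV, [Ca]i %.1f nM, [Na]i %.2f mM\n",
              x$final_state[["v"]], x$final_state[["ca_i"]] * 1e6,
              x$final_state[["na_i"]]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-cycle summaries of a simulation
#'
#' @param x a `ttmyo_sim` object.
#' @param ... unused.
#' @return the per-cycle tibble (end-diastolic values, cycle integrals and
#'   per-pool net Ca2+ amounts in amol/cycle).
#' @export
tidy.ttmyo_sim <- function(x, ...) x$cycles

#' One-row summary of a simulation
#'
#' @param x a `ttmyo_sim` object.
#' @param ... unused.
#' @return a one-row tibble with cycle count, simulated time and the final
#'   end-diastolic state of the main observables.
#' @export
glance.ttmyo_sim <- function(x, ...) {
  last <- dplyr::slice_tail(x$cycles, n = 1)
  tibble(
    n_cycles = nrow(x$cycles),
    t_total_s = last$t_end,
    v_end = last$v_end,
    ca_i_end = last$ca_i_end,
    na_i_end = last$na_i_end,
    k_c_end = last$k_c_end,
    ca_c_end = last$ca_c_end,
    n_ca_net_total = last$n_ca_net_s + last$n_ca_net_t
  )
}
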