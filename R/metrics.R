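# Derived per-cycle quantities: APD, Ca2+-transient areas, cycle Ca2+
# balance, end-diastolic series, exponential time-constant fits.

#' Action potential duration at a repolarization fraction
#'
#' The AP is timed from the instant of maximum upstroke velocity; the
#' repolarization level is `peak - fraction * (peak - diastolic)` with the
#' diastolic potential taken at the start of the trace, and the crossing
#' after the peak is located by linear interpolation.
#'
#' @param trace data frame with columns `time` (ms) and `v` (mV),
#'   covering one stimulated cycle.
#' @param fraction repolarization fraction (0.9 for APD90, 0.5 for APD50).
#' @return duration in ms, or `NA` (with attribute `reason = "no_ap"`) when
#'   no action potential is detected.
#' @export
apd <- function(trace, fraction = 0.9) {
  stopifnot(is.data.frame(trace), all(c("time", "v") %in% names(trace)))
  tt <- trace$time
  v <- trace$v
  dvdt <- diff(v) / diff(tt)
  i_up <- which.max(dvdt)
  # sub-sample upstroke timing: parabolic vertex through the three
  # derivative samples around the maximum
  t_mid <- (tt[-1] + tt[-length(tt)]) / 2
  t_up_refined <- t_mid[i_up]
  if (i_up > 1 && i_up < length(dvdt)) {
    y3 <- dvdt[(i_up - 1):(i_up + 1)]
    denom <- y3[1] - 2 * y3[2] + y3[3]
    if (abs(denom) > .Machine$double.eps) {
      shift <- 0.5 * (y3[1] - y3[3]) / denom
      h <- t_mid[i_up + 1] - t_mid[i_up]
      t_up_refined <- t_mid[i_up] + max(min(shift, 1), -1) * h
    }
  }
  v_dia <- v[1]
  i_peak <- which.max(v)
  v_peak <- v[i_peak]
  if (v_peak < v_dia + 20 || max(dvdt) < 1) {
    return(structure(NA_real_, reason = "no_ap"))
  }
  t_up <- t_up_refined
  level <- v_peak - fraction * (v_peak - v_dia)
  after <- seq(i_peak, length(v))
  below <- after[which(v[after] <= level)]
  if (!length(below)) return(structure(NA_real_, reason = "no_repolarization"))
  i2 <- below[1]
  if (i2 == i_peak) return(tt[i2] - t_up)
  i1 <- i2 - 1
  t_cross <- tt[i1] + (level - v[i1]) * (tt[i2] - tt[i1]) / (v[i2] - v[i1])
  t_cross - t_up
}

#' Relative change of the cytosolic Ca2+-transient whole-cycle integral
#'
#' Percentage change of the time integral of cytosolic `[Ca2+]` over a
#' whole cycle in a free-running simulation, relative to the matched cycle
#' of a reference simulation with extracellular concentrations fixed at
#' bulk values: `100 * (A_free - A_ref) / A_ref` (negative = reduction).
#'
#' @param free,reference either numeric cycle integrals (mM ms) or
#'   `ttmyo_sim` objects from which the integral of cycle `cycle` is taken.
#' @param cycle cycle index used when simulations are supplied.
#' @return percentage change (scalar).
#' @export
transient_area_change <- function(free, reference, cycle = NULL) {
  area <- function(x) {
    if (is.numeric(x)) return(x)
    stopifnot(inherits(x, "ttmyo_sim"))
    cyc <- if (is.null(cycle)) nrow(x$cycles) else cycle
    x$cycles$cai_area[x$cycles$cycle == cyc]
  }
  a_free <- area(free)
  a_ref <- area(reference)
  if (inherits(free, "ttmyo_sim") && inherits(reference, "ttmyo_sim")) {
    cyc <- if (is.null(cycle)) nrow(free$cycles) else cycle
    T_free <- with(free$cycles, t_end - t_start)[cyc]
    T_ref <- with(reference$cycles, t_end - t_start)[
      min(cyc, nrow(reference$cycles))]
    if (abs(T_free - T_ref) > 1e-9)
      abort("mismatched cycle lengths between free and reference runs")
  }
  100 * (a_free - a_ref) / a_ref
}

#' Net per-cycle Ca2+ transfer across one membrane pool
#'
#' Trapezoid-rule integral over one stimulation period of the
#' Ca2+-carrying currents of the requested membrane pool,
#' `(1/2F) * int(I_CaL - 2 I_NaCa + I_Cab + I_pCa) dt`, in amol/cycle
#' (positive = net outward transfer). This path is deliberately independent
#' of the in-solver quadrature accumulators, so the two can cross-check
#' each other.
#'
#' @param trace data frame holding a dense trace of exactly one cycle with
#'   columns `time` and the per-pool currents
#'   `i_cal_*`, `i_naca_*`, `i_bca_*`, `i_pca_*`.
#' @param pool `"surface"` or `"tubular"`.
#' @param period expected cycle length (ms); the trace must span it to
#'   within one sample.
#' @return net Ca2+ amount in amol/cycle.
#' @export
cycle_ca_balance <- function(trace, pool = c("surface", "tubular"),
                             period = NULL) {
  pool <- match.arg(pool)
  sfx <- if (pool == "tubular") "_t" else "_s"
  need <- paste0(c("i_cal", "i_naca", "i_bca", "i_pca"), sfx)
  stopifnot(all(c("time", need) %in% names(trace)))
  tt <- trace$time
  span <- max(tt) - min(tt)
  if (!is.null(period)) {
    dt_max <- max(diff(tt))
    if (abs(span - period) > dt_max + 1e-9)
      abort(sprintf("trace spans %.3f ms but one period is %.3f ms", span, period))
  }
  integ <- trace[[need[1]]] - 2 * trace[[need[2]]] +
    trace[[need[3]]] + trace[[need[4]]]
  trap <- sum(diff(tt) * (head(integ, -1) + tail(integ, -1)) / 2)
  trap * 1e3 / (2 * 96485)
}

#' Per-cycle end-diastolic series
#'
#' End-diastolic values (the state sampled immediately before each
#' stimulus) of selected observables, one row per delivered stimulus.
#'
#' @param sim a `ttmyo_sim` object (or its per-cycle tibble).
#' @param vars observable columns to keep (default: the cleft and first
#'   shell concentrations, membrane voltage and main intracellular levels).
#' @return tibble with `cycle`, `t_end` (s) and the requested columns.
#' @export
end_diastolic_series <- function(sim,
                                 vars = c("v_end", "ca_i_end", "na_i_end",
                                          "k_i_end", "ca_c_end", "k_c_end",
                                          "ca_t1_end", "k_t1_end",
                                          "ca_nsr_end")) {
  cyc <- if (inherits(sim, "ttmyo_sim")) sim$cycles else as_tibble(sim)
  keep <- intersect(vars, names(cyc))
  cyc[, c("cycle", "t_end", keep)]
}

#' Single-exponential time-constant fit
#'
#' Fits `y = a + b * exp(-t / tau)` by nonlinear least squares to a
#' monotone segment of a per-cycle series. The segment is chosen
#' automatically from the extremum of a running-mean smoothed copy of the
#' series: `direction = "decay"` fits from the extremum onward,
#' `"rise"` fits from the start to the extremum, `"all"` uses every point.
#'
#' @param series data frame with columns `t` (s) and `y`.
#' @param direction `"decay"`, `"rise"` or `"all"`.
#' @param smooth odd window length (samples) of the running mean used for
#'   extremum detection.
#' @return a `ttmyo_expfit` list: `tau` (same unit as `t`), `a`, `b`,
#'   `resid_norm`, `segment` (t-range used), `n` and the `nls` fit object.
#' @examples
#' tt <- seq(0, 200, by = 2)
#' fit <- fit_exponential_tau(data.frame(t = tt, y = 1 + 2 * exp(-tt / 46)))
#' fit$tau  # ~46
#' @export
fit_exponential_tau <- function(series, direction = c("decay", "rise", "all"),
                                smooth = 5) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(series), all(c("t", "y") %in% names(series)))
  ser <- series[order(series$t), c("t", "y")]
  if (nrow(ser) < 5) abort("need at least 5 points for an exponential fit")
  ys <- stats::filter(ser$y, rep(1 / smooth, smooth), sides = 2)
  ys[is.na(ys)] <- ser$y[is.na(ys)]
  i_ext <- if (direction == "all") 1L else if (direction == "decay") {
    # the segment relaxing toward the final level starts at the point
    # deviating most from that level (the series start for a pure decay,
    # the interior extremum for a rise-then-decay)
    which.max(abs(ys - ys[length(ys)]))
  } else {
    # the rise ends at the point deviating most from the starting level
    which.max(abs(ys - ys[1]))
  }
  seg <- switch(direction,
    decay = ser[i_ext:nrow(ser), ],
    rise = ser[seq_len(max(i_ext, 5)), ],
    all = ser
  )
  if (nrow(seg) < 5) abort("selected segment has fewer than 5 points")
  t0 <- seg$t[1]
  a0 <- seg$y[nrow(seg)]
  b0 <- seg$y[1] - a0
  if (abs(b0) < .Machine$double.eps^0.5) b0 <- sign(b0 + 1e-12) * 1e-6
  tau0 <- (seg$t[nrow(seg)] - t0) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a + b * exp(-(t - t0) / tau),
      data = cbind(seg, t0 = t0),
      start = list(a = a0, b = b0, tau = tau0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error"))
    abort(paste0("exponential fit did not converge: ", conditionMessage(fit)))
  cf <- coef(fit)
  structure(list(
    tau = unname(cf["tau"]), a = unname(cf["a"]), b = unname(cf["b"]),
    resid_norm = sqrt(sum(stats::residuals(fit)^2)),
    segment = range(seg$t), n = nrow(seg), fit = fit
  ), class = "ttmyo_expfit")
}

#' @export
print.ttmyo_expfit <- function(x, ...) {
  cat(sprintf("<ttmyo_expfit> tau = %.4g on [%.4g, %.4g] (n = %d, ||r|| = %.3g)\n",
              x$tau, x$segment[1], x$segment[2], x$n, x$resid_norm))
  invisible(x)
}

#' @rdname fit_exponential_tau
#' @param x a `ttmyo_expfit` object.
#' @param ... unused.
#' @export
tidy.ttmyo_expfit <- function(x, ...) {
  tibble(term = c("a", "b", "tau"),
         estimate = c(x$a, x$b, x$tau))
}

#' @rdname fit_exponential_tau
#' @export
glance.ttmyo_expfit <- function(x, ...) {
  tibble(tau = x$tau, resid_norm = x$resid_norm, n = x$n,
         t_min = x$segment[1], t_max = x$segment[2])
}
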