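# State vector layout, packing and the quiescent initial state.

#' State vector layout manifest
#'
#' The full ODE state: membrane voltage, gating/Markov occupancies,
#' intracellular concentrations and buffer occupancies, the three-ion
#' nine-shell t-tubular profile, the cleft concentrations, and per-cycle
#' integral accumulators used for cycle metrics.
#'
#' @return a list with `version`, `n_state`, `names`, and index helpers for
#'   the main blocks (`tubular`, `cleft`, `accumulators`, `markov`).
#' @export
state_layout <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cache <<- .state_layout_build()
    cache
  }
})

.state_layout_build <- function() {
  nm <- .Call("c_state_names", PACKAGE = "ttmyo")
  list(
    version = 1L,
    n_state = length(nm),
    names = nm,
    markov = list(
      na_activation = grep("^na_m", nm, value = TRUE),
      cal_activation = grep("^cal_c|^cal_o$", nm, value = TRUE),
      ryr = grep("^ryr_", nm, value = TRUE)
    ),
    gates_hh = c("na_h", "na_j", "cal_f", "cal_f2", "cal_fcass",
                 "kto_r", "kto_s", "kr_xr1", "kr_xr2", "ks_xs"),
    tubular = grep("_t[1-9]$", nm, value = TRUE),
    cleft = c("ca_c", "k_c", "na_c"),
    accumulators = grep("^int_", nm, value = TRUE)
  )
}

#' Names of the auxiliary model outputs (currents and SR fluxes)
#' @return character vector of auxiliary output names (per-pool currents in
#'   pA, SR fluxes in fmol/ms).
#' @export
aux_names <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- .Call("c_aux_names", PACKAGE = "ttmyo")
    cache
  }
})

# crude but adequate starting guess for relaxation to quiescence;
# extracellular compartments start at bulk, gates near their resting values
.default_start <- function(params) {
  lay <- state_layout()
  y <- setNames(numeric(lay$n_state), lay$names)
  y["v"] <- -86
  y["na_m0"] <- 1
  y["na_h"] <- 0.99
  y["na_j"] <- 0.99
  y["cal_c0"] <- 1
  y["cal_f"] <- 1
  y["cal_f2"] <- 1
  y["cal_fcass"] <- 1
  y["kto_s"] <- 1
  y["kr_xr2"] <- 0.45
  y["ryr_c1"] <- 1
  y["ca_i"] <- 6.4e-5
  y["ca_d"] <- 6.4e-5
  y["ca_nsr"] <- 0.25
  y["ca_jsr"] <- 0.25
  y["b_cm"] <- with(params, cmdn_tot * 6.4e-5 / (6.4e-5 + cmdn_koff / cmdn_kon))
  y["b_htrpn"] <- with(params, htrpn_tot * 6.4e-5 / (6.4e-5 + htrpn_koff / htrpn_kon))
  y["b_ltrpn"] <- with(params, ltrpn_tot * 6.4e-5 / (6.4e-5 + ltrpn_koff / ltrpn_kon))
  y["b_cs"] <- with(params, csqn_tot * 0.25 / (0.25 + csqn_koff / csqn_kon))
  y["na_i"] <- 9.3
  y["k_i"] <- 138
  y[grep("^ca_t", lay$names, value = TRUE)[1:9]] <- params$ca_b
  y[paste0("k_t", 1:9)] <- params$k_b
  y[paste0("na_t", 1:9)] <- params$na_b
  y["ca_c"] <- params$ca_b
  y["k_c"] <- params$k_b
  y["na_c"] <- params$na_b
  y
}

# scaled derivative norm used as the quiescence criterion (1/ms);
# accumulators are excluded, concentrations scaled by their magnitude
.deriv_norm <- function(y, dy, lay) {
  keep <- setdiff(lay$names, lay$accumulators)
  scale <- pmax(abs(y[keep]), 1e-4)
  max(abs(dy[keep]) / scale)
}

#' Quiescent initial state of the model
#'
#' Integrates the unstimulated model from a stored near-equilibrium seed
#' (or a generic guess) until the scaled derivative norm falls below `tol`,
#' i.e. until the cell is at its quiescent equilibrium with all
#' extracellular compartments equilibrated at bulk concentrations.
#'
#' With the basic parameter set the equilibrium has a resting cytosolic
#' Ca2+ concentration near 63.6 nM and intracellular Na+ near 9.3 mM.
#'
#' @param params a `ttmyo_params` object.
#' @param tol convergence tolerance on the scaled derivative norm (1/ms).
#' @param max_s maximum simulated rest time (s) before giving up.
#' @param start optional starting state vector (defaults to the stored seed
#'   when the parameter set is the basic one).
#' @return named state vector at quiescent equilibrium.
#' @export
initial_state <- function(params, tol = 1e-9, max_s = 4000, start = NULL) {
  params <- validate_parameters(params)
  lay <- state_layout()
  y <- start
  if (is.null(y) && exists(".resting_seed_basic") &&
      length(.resting_seed_basic) == lay$n_state &&
      isTRUE(all.equal(param_vector(params)[c("g_bna", "g_bca", "i_nak_max")],
                       .resting_seed_params[c("g_bna", "g_bca", "i_nak_max")],
                       tolerance = 1e-12))) {
    y <- setNames(as.numeric(.resting_seed_basic), lay$names)
  }
  if (is.null(y)) y <- .default_start(params)
  pvec <- param_vector(params)
  pvec["stim_amp"] <- 0
  t_done <- 0
  chunk <- 20000  # ms
  repeat {
    ev <- .rhs_eval(0, y, pvec)
    if (.deriv_norm(y, ev$derivatives, lay) < tol) break
    if (t_done >= max_s * 1000)
      abort(sprintf(
        "initial_state did not converge within %g s (scaled |dy| = %.3g)",
        max_s, .deriv_norm(y, ev$derivatives, lay)))
    y <- .integrate_span(y, 0, chunk, pvec)$y_end
    y[state_layout()$accumulators] <- 0
    t_done <- t_done + chunk
    chunk <- min(chunk * 2, 4e5)
  }
  y[lay$accumulators] <- 0
  y
}
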