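# Sarcolemmal currents: per-pool evaluation, gating kinetics, reversal
# potentials and the ion-species charge ledger.

#' Nernst reversal potential
#'
#' @param valence ionic valence (e.g. 1 for K+, 2 for Ca2+).
#' @param c_out,c_in extracellular and intracellular concentrations (mM),
#'   both strictly positive.
#' @param temperature absolute temperature (K).
#' @return reversal potential in mV.
#' @examples
#' reversal_potential(1, 5.4, 130)  # about -84.9 mV
#' @export
reversal_potential <- function(valence, c_out, c_in, temperature = 310) {
  if (any(c_out <= 0) || any(c_in <= 0))
    abort("invalid state: concentrations must be strictly positive")
  8314 * temperature / (valence * 96485) * log(c_out / c_in)
}

# which ion species each current family carries, with its charge multiplier
# (used for the per-pool mass-balance ledger; pumps/exchangers carry more
# than one species)
.species_map <- function() {
  tibble(
    family = c("i_na", "i_naps", "i_bna", "i_nsna", "i_nak", "i_naca",
               "i_kto", "i_kr", "i_ks", "i_k1", "i_kna", "i_nsk", "i_nak",
               "i_cal", "i_bca", "i_pca", "i_naca"),
    species = c(rep("Na", 6), rep("K", 7), rep("Ca", 4)),
    multiplier = c(1, 1, 1, 1, 3, 3,
                   1, 1, 1, 1, 1, 1, -2,
                   1, 1, 1, -2)
  )
}

#' Evaluate all membrane current families for both membrane pools
#'
#' The tubular pool is driven by the concentrations of the first t-tubular
#' shell, the surface pool by the cleft concentrations; both share the
#' single membrane potential and gating state. Conductance-scaled families
#' split between the pools by their t-tubular fractions.
#'
#' @param state named state vector.
#' @param params a `ttmyo_params` object.
#' @param clamp,stim_amp passed to [assemble_rhs()].
#' @return a tibble with one row per current family and pool: `family`,
#'   `pool` (`"surface"`/`"tubular"`), `current` (pA) and `total` per
#'   family.
#' @export
membrane_currents <- function(state, params, clamp = clamp_config("free"),
                              stim_amp = 0) {
  aux <- assemble_rhs(state, params, clamp, stim_amp)$aux
  nm <- names(aux)
  split_nm <- nm[grepl("_s$|_t$", nm) & grepl("^i_", nm)]
  fam <- sub("_[st]$", "", split_nm)
  out <- tibble(
    family = fam,
    pool = ifelse(grepl("_t$", split_nm), "tubular", "surface"),
    current = unname(aux[split_nm])
  )
  out <- dplyr::group_by(out, .data$family)
  out <- dplyr::mutate(out, total = sum(.data$current))
  dplyr::ungroup(out)
}

#' Per-species membrane charge flux ledger
#'
#' Sums, for each ion species and membrane pool, the charge carried across
#' the membrane by all current families (Na+, K+, Ca2+ with pump/exchanger
#' stoichiometries applied). By construction the Na + K + Ca totals equal
#' the total ionic membrane current.
#'
#' @inheritParams membrane_currents
#' @return tibble with `species`, `pool`, `i_charge` (pA, outward
#'   positive).
#' @export
species_currents <- function(state, params, clamp = clamp_config("free"),
                             stim_amp = 0) {
  aux <- assemble_rhs(state, params, clamp, stim_amp)$aux
  map <- .species_map()
  res <- tidyr::expand_grid(map, pool = c("surface", "tubular"))
  res$current <- aux[paste0(res$family, ifelse(res$pool == "tubular", "_t", "_s"))]
  res <- dplyr::group_by(res, .data$species, .data$pool)
  res <- dplyr::summarise(res,
                          i_charge = sum(.data$multiplier * .data$current),
                          .groups = "drop")
  res
}

#' Time derivatives of the gating and Markov states
#'
#' @param state named state vector.
#' @param params a `ttmyo_params` object.
#' @return named numeric vector of derivatives (per ms) for all
#'   Hodgkin-Huxley gates and Markov occupancies.
#' @export
gating_derivatives <- function(state, params) {
  lay <- state_layout()
  gates <- c(unlist(lay$markov, use.names = FALSE), lay$gates_hh)
  assemble_rhs(state, params)$derivatives[gates]
}

#' Transition-rate matrix of a Markov gating scheme
#'
#' Reconstructs the (occupancy-linear) transition-rate matrix Q of one of
#' the model's Markov chains at the operating point given by `state`, by
#' evaluating the compiled right-hand side on unit occupancy vectors, so
#' that d(occupancy)/dt = Q occupancy. Rates depend on the membrane
#' potential (and, for the RyR, on dyadic Ca2+) stored in `state`.
#'
#' @param chain one of `"na_activation"`, `"cal_activation"`, `"ryr"`.
#' @param state named state vector providing the operating point.
#' @param params a `ttmyo_params` object.
#' @return square matrix Q with columns summing to zero.
#' @export
markov_matrix <- function(chain = c("na_activation", "cal_activation", "ryr"),
                          state, params) {
  chain <- match.arg(chain)
  lay <- state_layout()
  idx <- lay$markov[[chain]]
  pvec <- param_vector(validate_parameters(params))
  q <- matrix(0, length(idx), length(idx), dimnames = list(idx, idx))
  for (j in seq_along(idx)) {
    y <- state
    y[idx] <- 0
    y[idx[j]] <- 1
    q[, j] <- .rhs_eval(0, y, pvec)$derivatives[idx]
  }
  q
}

#' Voltage-dependent equilibrium of a Markov chain
#'
#' Null-space (stationary) occupancy distribution of [markov_matrix()].
#'
#' @inheritParams markov_matrix
#' @return named numeric vector of stationary occupancies summing to 1.
#' @export
markov_equilibrium <- function(chain, state, params) {
  q <- markov_matrix(chain, state, params)
  # stationary distribution: null vector of Q with unit sum
  ns <- svd(q)$v[, ncol(q)]
  ns <- ns / sum(ns)
  setNames(ns, colnames(q))
}
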