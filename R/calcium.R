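# Intracellular Ca2+ handling: buffers and SR fluxes.

#' Buffer binding fluxes and equilibrium occupancies
#'
#' Mass-action binding rates of the four endogenous Ca2+ buffers:
#' calmodulin, high- and low-affinity troponin sites (cytosol) and
#' calsequestrin (junctional SR).
#'
#' @param state named state vector.
#' @param params a `ttmyo_params` object.
#' @return tibble with one row per buffer: free ligand concentration seen
#'   by the buffer, bound and total buffer (mM), `kon`, `koff`, `kd`, the
#'   net binding flux (mM/ms) and the equilibrium occupancy
#'   `c / (c + kd)`.
#' @export
buffer_fluxes <- function(state, params) {
  params <- validate_parameters(params)
  buf <- tibble(
    buffer = c("calmodulin", "troponin_high", "troponin_low", "calsequestrin"),
    state_name = c("b_cm", "b_htrpn", "b_ltrpn", "b_cs"),
    ligand = c(state[["ca_i"]], state[["ca_i"]], state[["ca_i"]],
               state[["ca_jsr"]]),
    total = c(params$cmdn_tot, params$htrpn_tot, params$ltrpn_tot,
              params$csqn_tot),
    kon = c(params$cmdn_kon, params$htrpn_kon, params$ltrpn_kon,
            params$csqn_kon),
    koff = c(params$cmdn_koff, params$htrpn_koff, params$ltrpn_koff,
             params$csqn_koff)
  )
  buf$bound <- unname(state[buf$state_name])
  buf$kd <- buf$koff / buf$kon
  buf$flux <- buf$kon * buf$ligand * (buf$total - buf$bound) -
    buf$koff * buf$bound
  buf$occupancy_eq <- buf$ligand / (buf$ligand + buf$kd)
  buf[, c("buffer", "ligand", "total", "bound", "kon", "koff", "kd",
          "flux", "occupancy_eq")]
}

#' Sarcoplasmic-reticulum Ca2+ fluxes
#'
#' SERCA uptake (cytosol to NSR), RyR release (JSR to dyadic space),
#' NSR-to-JSR transfer and dyad-to-cytosol transfer, each as an absolute
#' flux in fmol/ms (volume factors already applied).
#'
#' @param state named state vector.
#' @param params a `ttmyo_params` object.
#' @return named list with `j_up`, `j_rel`, `j_tr`, `j_xfer` (fmol/ms).
#' @export
sr_fluxes <- function(state, params) {
  aux <- assemble_rhs(state, params)$aux
  as.list(aux[c("j_up", "j_rel", "j_tr", "j_xfer")])
}
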