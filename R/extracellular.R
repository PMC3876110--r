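# Restricted extracellular spaces: t-tubular shells and cleft exchange.

#' Radial diffusion derivatives over the t-tubular shells
#'
#' Diffusive exchange between adjacent concentric shells of the t-tubular
#' lumen (no membrane sources, no mouth exchange): the flux across the
#' interface between shell k and k+1 is proportional to their concentration
#' difference with conductance `D_eff * A_interface / dr`.
#'
#' @param profile numeric vector of shell concentrations (mM), element 1
#'   adjacent to the membrane.
#' @param params a `ttmyo_params` object.
#' @param ion one of `"ca"`, `"k"`, `"na"` selecting the effective radial
#'   diffusion coefficient.
#' @return numeric vector of concentration derivatives (mM/ms).
#' @export
radial_diffusion_rhs <- function(profile, params, ion = c("ca", "k", "na")) {
  ion <- match.arg(ion)
  params <- validate_parameters(params)
  n <- length(profile)
  d_eff <- params[[paste0("d_rad_", ion)]]          # cm^2/s
  a_cm <- params$tt_radius * 1e-4
  vtt_cm3 <- params$v_tt * 1e-9
  len <- vtt_cm3 / (pi * a_cm^2)
  dr <- a_cm / n
  r_in <- a_cm * (n - seq_len(n)) / n               # inner radius, shell k
  g <- d_eff * 2 * pi * r_in[-n] * len / dr * 1e6   # pL/ms
  vsh <- params$v_tt * ((n - seq_len(n) + 1)^2 - (n - seq_len(n))^2) / n^2
  dcdt <- numeric(n)
  for (k in seq_len(n)) {
    f <- 0
    if (k > 1) f <- f + g[k - 1] * (profile[k - 1] - profile[k])
    if (k < n) f <- f + g[k] * (profile[k + 1] - profile[k])
    dcdt[k] <- f / vsh[k]
  }
  dcdt
}

#' Exchange flux between two well-stirred compartments
#'
#' First-order exchange `flux = volume_from * (c_from - c_to) / tau`
#' (fmol/ms for mM and pL inputs), applied with opposite signs to the two
#' compartments; an infinite reservoir simply ignores its share.
#'
#' @param c_from,c_to concentrations (mM).
#' @param volume_from volume of the donor compartment (pL).
#' @param tau exchange time constant (ms), > 0.
#' @return flux in fmol/ms (positive = from -> to).
#' @export
compartment_exchange <- function(c_from, c_to, volume_from, tau) {
  if (any(tau <= 0)) abort("tau must be > 0")
  volume_from * (c_from - c_to) / tau
}

#' Volume-weighted mean t-tubular concentration
#'
#' @param profile numeric vector of shell concentrations (mM), or a
#'   `ttmyo_sim` state vector together with an ion prefix.
#' @param volumes shell volumes (pL); defaults to the nine-shell volumes of
#'   the basic geometry when `params` is given instead.
#' @param params optional `ttmyo_params` used to derive `volumes`.
#' @return volume-weighted mean concentration (mM).
#' @export
mean_tubular_concentration <- function(profile, volumes = NULL, params = NULL) {
  if (is.null(volumes)) {
    if (is.null(params)) abort("provide shell `volumes` or `params`")
    volumes <- shell_volumes(validate_parameters(params))
  }
  if (length(profile) != length(volumes))
    abort("profile and volumes must have equal length")
  sum(profile * volumes) / sum(volumes)
}

#' Extract the t-tubular concentration profiles from a state vector
#'
#' @param state named state vector.
#' @return tibble with `shell` (1 = adjacent to the membrane), `ca`, `k`,
#'   `na` (mM).
#' @export
tubular_profile <- function(state) {
  tibble(
    shell = 1:9,
    ca = unname(state[paste0("ca_t", 1:9)]),
    k = unname(state[paste0("k_t", 1:9)]),
    na = unname(state[paste0("na_t", 1:9)])
  )
}
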