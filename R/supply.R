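# The steady-state supply function of the SPA model.
#
# At steady state the same flux E passes through every series element, so the
# tension drop across element i satisfies  F_i(P_out) - F_i(P_in) = E  where
# F_i is the element's cumulative flux integral. Chaining the exact inverses
# (see vulnerability.R) from the soil tension upward yields the canopy
# tension that carries E, and differentiating the chain gives the
# instantaneous supply slope K = dE/dpsi_canopy.

chain_caps <- function(net, psi_s) {
  vapply(net$pack, function(el) el$cap - pack_F(el, psi_s), numeric(1))
}

#' Canopy tension required to carry a steady-state flux
#'
#' @param E steady-state flux (mol m-2 basal area s-1); vectorised
#' @param net a [plant_network()]
#' @param psi_soil_tension soil tension (MPa, >= 0; magnitude of the soil
#'   water potential)
#' @return canopy tension (MPa) per flux; `Inf` where the flux exceeds the
#'   continuum's capacity
#' @export
canopy_tension <- function(E, net, psi_soil_tension = 0) {
  stopifnot(inherits(net, "plant_network"), psi_soil_tension >= 0)
  if (any(E < 0)) stop("flux must be non-negative")
  P <- rep_len(psi_soil_tension, length(E))
  for (el in net$pack) {
    P <- pack_Finv(el, pack_F(el, P) + E)
  }
  P
}

#' Supply-function slope dE/dpsi at the operating point carrying flux E
#'
#' The chain rule across series elements gives
#' `s_i = (k_i(P_in) s_{i-1} + 1) / k_i(P_out)` with `s_0 = 0`, and
#' `K = 1/s_N`. At `E = 0` this reduces to the series harmonic conductance at
#' the soil tension.
#'
#' @inheritParams canopy_tension
#' @return slope K (mol m-2 s-1 MPa-1); 0 where the flux is infeasible
#' @export
supply_slope <- function(E, net, psi_soil_tension = 0) {
  stopifnot(inherits(net, "plant_network"), psi_soil_tension >= 0)
  if (any(E < 0)) stop("flux must be non-negative")
  chain_slope(E, net$pack, psi_soil_tension)
}

chain_slope <- function(E, pack, psi_s) {
  P <- rep_len(psi_s, length(E))
  s <- rep_len(0, length(E))
  for (el in pack) {
    k_in <- pack_k(el, P)
    P <- pack_Finv(el, pack_F(el, P) + E)
    feas <- is.finite(P)
    k_out <- rep_len(NA_real_, length(E))
    k_out[feas] <- pack_k(el, P[feas])
    s <- ifelse(feas, (k_in * s + 1) / k_out, Inf)
  }
  out <- 1 / s
  out[!is.finite(P)] <- 0
  out
}

#' Steady-state supply flux at a given canopy tension
#'
#' Inverts [canopy_tension()] by bracketed root finding. The supply function
#' is zero at `psi_canopy = psi_soil`, non-decreasing, and saturates at the
#' critical flux.
#'
#' @param psi_canopy_tension canopy tension (MPa), must be >= the soil tension
#' @inheritParams canopy_tension
#' @param tol root tolerance on tension (MPa)
#' @return flux E (mol m-2 basal area s-1)
#' @export
supply_flux <- function(psi_canopy_tension, net, psi_soil_tension = 0,
                        tol = 1e-10) {
  stopifnot(inherits(net, "plant_network"))
  if (psi_canopy_tension < psi_soil_tension) {
    stop("canopy tension must be at least the soil tension")
  }
  if (psi_canopy_tension == psi_soil_tension) return(0)
  e_hi <- min(chain_caps(net, psi_soil_tension))
  if (!is.finite(e_hi)) {
    # no embolism limit anywhere: linear-dominated; expand a finite bracket
    e_hi <- net$k_total_max * (psi_canopy_tension - psi_soil_tension)
    while (canopy_tension(e_hi, net, psi_soil_tension) < psi_canopy_tension) {
      e_hi <- e_hi * 2
    }
  } else {
    e_hi <- e_hi * (1 - 1e-12)
  }
  f <- function(E) {
    p <- canopy_tension(E, net, psi_soil_tension)
    min(p, 1e9) - psi_canopy_tension
  }
  if (f(e_hi) < 0) return(e_hi)  # tension beyond saturation: flux at capacity
  stats::uniroot(f, c(0, e_hi), tol = tol)$root
}

#' Critical flux of the supply function
#'
#' The flux at which the marginal supply slope has fallen below
#' `slope_frac` of its value at zero flux: the effective upper bound of
#' regulated transpiration. Networks with no embolism limit (all elements
#' constant-conductance) have no finite critical flux; the flux at the
#' configured maximum tension `psi_max` is then returned with
#' `finite = FALSE`.
#'
#' @inheritParams canopy_tension
#' @param slope_frac fraction of the initial slope defining saturation
#' @param psi_max cap on canopy tension (MPa) for unbounded supply functions
#' @return list with `E_crit`, logical `finite`, and `K0` (initial slope)
#' @export
critical_flux <- function(net, psi_soil_tension = 0, slope_frac = 1e-6,
                          psi_max = 40) {
  stopifnot(inherits(net, "plant_network"))
  K0 <- supply_slope(0, net, psi_soil_tension)
  e_cap <- min(chain_caps(net, psi_soil_tension))
  if (!is.finite(e_cap)) {
    e_at_psimax <- supply_flux(psi_max, net, psi_soil_tension)
    return(list(E_crit = e_at_psimax, finite = FALSE, K0 = K0))
  }
  e_hi <- e_cap * (1 - 1e-12)
  if (canopy_tension(e_hi, net, psi_soil_tension) > psi_max) {
    e_hi <- min(e_hi, supply_flux(psi_max, net, psi_soil_tension))
  }
  target <- slope_frac * K0
  if (supply_slope(e_hi, net, psi_soil_tension) > target) {
    # slope still above threshold at the tension cap
    return(list(E_crit = e_hi, finite = FALSE, K0 = K0))
  }
  root <- stats::uniroot(function(E) supply_slope(E, net, psi_soil_tension) - target,
                         c(0, e_hi), tol = 1e-12 * max(e_hi, 1))$root
  list(E_crit = root, finite = TRUE, K0 = K0)
}
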