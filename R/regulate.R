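#' Linear flood-response model for a physiological condition
#'
#' A shared-intercept linear trajectory: the condition equals `intercept` at
#' duration zero in both treatments and changes by `slope_control` or
#' `slope_flood` units per day thereafter. These are the per-condition rows
#' of the harvested-plant analysis and drive the flood impairment of
#' `k_total_max` in the SPA model.
#'
#' @param intercept condition value at duration 0 (condition units)
#' @param slope_control change per day in the control treatment
#' @param slope_flood change per day in the flood treatment
#' @param condition label, e.g. `"k_total"` or `"k_root"`
#' @return an object of class `flood_response`
#' @export
flood_response_model <- function(intercept, slope_control, slope_flood,
                                 condition = "k_total") {
  stopifnot(is.finite(intercept), is.finite(slope_control),
            is.finite(slope_flood))
  structure(list(intercept = intercept, slope_control = slope_control,
                 slope_flood = slope_flood, condition = condition),
            class = "flood_response")
}

#' Flood impairment scale after t days of waterlogging
#'
#' `relative_to_control` divides the flood trajectory by the control
#' trajectory, `s(t) = (a + s_f t) / (a + s_c t)`: the impairment is
#' expressed against what the same plants would have done unflooded.
#' `relative_to_intercept` divides by the (constant) shared intercept.
#' The result is clamped to `[floor, 1]`; the linear trajectories are an
#' approximation that goes negative at long durations.
#'
#' @param t flood duration (days, >= 0); vectorised
#' @param frm a [flood_response_model()]
#' @param mode `"relative_to_control"` or `"relative_to_intercept"`
#' @param floor lower clamp for the scale
#' @return impairment fraction in `[floor, 1]`
#' @export
#' @examples
#' frm <- flood_response_model(3.96, 0.103, -0.178)
#' flood_scale(c(0, 10, 25), frm)
flood_scale <- function(t, frm,
                        mode = c("relative_to_control", "relative_to_intercept"),
                        floor = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(inherits(frm, "flood_response"))
  if (any(t < 0)) stop("flood duration must be non-negative")
  num <- frm$intercept + frm$slope_flood * t
  den <- if (mode == "relative_to_control") {
    frm$intercept + frm$slope_control * t
  } else {
    rep_len(frm$intercept, length(t))
  }
  if (any(den <= 0)) {
    stop("control trajectory is non-positive on the evaluated range; ",
         "the impairment ratio is undefined")
  }
  pmin(pmax(num / den, floor), 1)
}

#' Regulated canopy conductance at one environmental state
#'
#' Implements the supply-demand closure: the plant operates at the unique
#' flux `E` in `[0, E_crit]` satisfying
#' \deqn{E = \hat D \, G_{max} \, K(E)/K_0,}
#' where \eqn{\hat D} is VPD as a mole fraction, \eqn{K(E)} the supply-function
#' slope at the canopy tension carrying `E`, and \eqn{K_0} the slope at zero
#' flux (evaluated at the prevailing soil tension). The realised canopy
#' conductance is \eqn{G = G_{max} K/K_0}: stomata close in proportion to the
#' loss of marginal hydraulic capacity.
#'
#' @param env a list or one-row data frame with `vpd` (kPa) and `psi_soil`
#'   (MPa, <= 0); other fields are ignored
#' @param net a [plant_network()]
#' @param scale_applied flood impairment already applied to `net` (recorded in
#'   the output, not used in computation)
#' @param tol_frac relative tolerance of the fixed point (fraction of E_crit)
#' @return a list of class `spa_prediction`: `g_canopy` (kg hr-1 m-2 basal
#'   area per mole fraction), `e_flux` (kg hr-1 m-2), `psi_canopy` (tension,
#'   MPa), `scale_applied`
#' @export
regulated_conductance <- function(env, net, scale_applied = 1,
                                  tol_frac = 1e-9) {
  stopifnot(inherits(net, "plant_network"))
  vpd <- env$vpd
  psi_soil <- if (is.null(env$psi_soil)) 0 else env$psi_soil
  if (is.na(vpd) || vpd < 0) stop("vpd must be non-negative")
  if (psi_soil > 0) stop("psi_soil is a water potential and must be <= 0")
  psi_s <- -psi_soil
  D <- vpd_mole_fraction(vpd)

  K0 <- supply_slope(0, net, psi_s)
  if (D <= 0) {
    return(structure(list(g_canopy = net$G_max, e_flux = 0,
                          psi_canopy = psi_s, scale_applied = scale_applied),
                     class = "spa_prediction"))
  }
  demand_mol <- function(E) {
    D * net$G_max * (chain_slope(E, net$pack, psi_s) / K0) / KG_HR_PER_MOL_S
  }
  f <- function(E) E - demand_mol(E)
  # bracket at (just inside) the supply capacity, where K ~ 0; unbounded
  # networks fall back to the flux at a 40 MPa tension cap
  e_hi <- min(chain_caps(net, psi_s))
  e_hi <- if (is.finite(e_hi)) e_hi * (1 - 1e-12) else supply_flux(40, net, psi_s)
  if (f(e_hi) < 0) {
    # demand still exceeds supply at the bracket end (tension-capped network):
    # operate at the cap
    e_star <- e_hi
  } else {
    e_star <- stats::uniroot(f, c(0, e_hi), tol = tol_frac * max(e_hi, 1))$root
  }
  K <- chain_slope(e_star, net$pack, psi_s)
  g <- net$G_max * K / K0
  structure(list(g_canopy = g,
                 e_flux = mol_s_to_kg_hr(e_star),
                 psi_canopy = canopy_tension(e_star, net, psi_s),
                 scale_applied = scale_applied),
            class = "spa_prediction")
}

#' Predict a canopy-conductance timeseries with flood impairment
#'
#' For each day in the environment series, the flood-duration-dependent
#' impairment scale is computed (1 before the flood window; `s(t)` within it;
#' after it, either frozen at the end-of-flood value, matching the observed
#' lack of recovery, or relaxed linearly back to 1 over `recover_days`),
#' applied to the network, and the regulated conductance solved.
#'
#' @param env_series data frame with columns `day`, `vpd`, `psi_soil` (and
#'   optionally others), sorted by day
#' @param net a [plant_network()]
#' @param frm a [flood_response_model()] driving the impairment, or `NULL`
#'   for an unflooded (control) plant
#' @param flood_window numeric `c(start, end)` in days
#' @param mode passed to [flood_scale()]
#' @param target passed to [apply_flood()]
#' @param post_flood `"persist"` or `"recover"`
#' @param recover_days days over which the scale relaxes back to 1 when
#'   `post_flood = "recover"`
#' @param floor lower clamp for the scale
#' @return data frame with `day`, `g_canopy`, `e_flux`, `psi_canopy`, `scale`
#' @export
predict_timeseries <- function(env_series, net, frm = NULL,
                               flood_window = c(0, 26),
                               mode = "relative_to_control",
                               target = "whole_plant",
                               post_flood = c("persist", "recover"),
                               recover_days = 14,
                               floor = 1e-3) {
  post_flood <- match.arg(post_flood)
  if (is.null(env_series) || nrow(env_series) == 0L) {
    stop("environment series is empty")
  }
  if (is.unsorted(env_series$day)) stop("environment series must be sorted by day")
  scales <- rep_len(1, nrow(env_series))
  if (!is.null(frm)) {
    t_end <- flood_window[2] - flood_window[1]
    s_end <- flood_scale(t_end, frm, mode, floor)
    for (i in seq_len(nrow(env_series))) {
      d <- env_series$day[i]
      if (d < flood_window[1]) {
        scales[i] <- 1
      } else if (d <= flood_window[2]) {
        scales[i] <- flood_scale(d - flood_window[1], frm, mode, floor)
      } else if (post_flood == "persist") {
        scales[i] <- s_end
      } else {
        frac <- min((d - flood_window[2]) / recover_days, 1)
        scales[i] <- s_end + (1 - s_end) * frac
      }
    }
  }
  out <- lapply(seq_len(nrow(env_series)), function(i) {
    n <- if (scales[i] < 1) apply_flood(net, scales[i], target) else net
    p <- regulated_conductance(env_series[i, , drop = FALSE], n,
                               scale_applied = scales[i])
    data.frame(day = env_series$day[i], g_canopy = p$g_canopy,
               e_flux = p$e_flux, psi_canopy = p$psi_canopy,
               scale = scales[i])
  })
  do.call(rbind, out)
}
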