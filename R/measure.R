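# Conductance and scaling calculations for the raw greenhouse measurements.

#' Hydraulic conductance from a vacuum-chamber pressure-flow series
#'
#' The vacuum-chamber protocol applies a pressure sequence (e.g. 0, 20, 40,
#' 0 kPa) and records the solution uptake rate at each step; conductance is
#' the least-squares slope of flow against pressure, standardised by stem
#' basal area. Repeated zero-pressure points enter the regression as ordinary
#' observations. The intercept is unconstrained and absorbs background flow.
#'
#' @param pressures applied vacuum pressures (kPa), length >= 3
#' @param flows solution uptake rates (volume per second), same length
#' @param basal_area stem cross-sectional area (mm2), > 0
#' @return list: `k` (conductance per basal area), `slope` (raw flow/pressure
#'   slope), `intercept`, `valid` (FALSE when the fitted slope is not
#'   positive, flagging an unusable measurement)
#' @export
#' @examples
#' k_from_pressure_flow(c(0, 20, 40, 0), c(0, 1, 2, 0), basal_area = 20)
k_from_pressure_flow <- function(pressures, flows, basal_area) {
  stopifnot(length(pressures) == length(flows), length(pressures) >= 3)
  if (any(pressures < 0)) stop("pressures must be non-negative")
  if (basal_area <= 0) stop("basal_area must be positive")
  if (stats::var(pressures) == 0) stop("zero pressure variance: slope undefined")
  fit <- stats::lm(flows ~ pressures)
  slope <- unname(stats::coef(fit)[2])
  list(k = slope / basal_area,
       slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       valid = slope > 0)
}

#' Whole-plant conductance from leaf-level transpiration and water potential
#'
#' `k_total = E / (psi_soil - psi_leaf)` on the leaf-area basis, with
#' `psi_soil = 0` for soils kept at or near saturation.
#'
#' @param e_leaf transpiration per leaf area (mmol m-2 s-1), >= 0
#' @param psi_leaf leaf water potential (MPa, < psi_soil)
#' @param psi_soil soil water potential (MPa, default 0)
#' @return conductance (mmol m-2 s-1 MPa-1), positive
#' @export
k_total_leaf_level <- function(e_leaf, psi_leaf, psi_soil = 0) {
  if (any(psi_leaf >= psi_soil)) {
    stop("psi_leaf must be below psi_soil for a defined conductance")
  }
  e_leaf / (psi_soil - psi_leaf)
}

#' Scale a leaf-area-based quantity to the basal-area basis
#'
#' Multiplies by total leaf area (m2) and divides by stem basal area (mm2,
#' converted to m2). Used to convert leaf-level transpiration or stomatal
#' conductance to the whole-plant basis the SPA model works on.
#'
#' @param x quantity per m2 leaf area
#' @param leaf_area total leaf area (m2), > 0
#' @param basal_area stem basal area (mm2), > 0
#' @return quantity per m2 basal area
#' @export
scale_to_basal <- function(x, leaf_area, basal_area) {
  if (any(leaf_area <= 0) || any(basal_area <= 0)) {
    stop("areas must be positive")
  }
  x * leaf_area / (basal_area * 1e-6)
}

#' @rdname scale_to_basal
#' @param x_basal quantity per m2 basal area
#' @export
unscale_from_basal <- function(x_basal, leaf_area, basal_area) {
  if (any(leaf_area <= 0) || any(basal_area <= 0)) {
    stop("areas must be positive")
  }
  x_basal * (basal_area * 1e-6) / leaf_area
}
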