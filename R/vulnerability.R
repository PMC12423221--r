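#' Xylem vulnerability curve
#'
#' A two-parameter Weibull vulnerability curve,
#' \deqn{k(P) = k_{max} \exp(-(P/b)^c),}
#' describing the decline of a hydraulic component's conductance with
#' increasing xylem tension \eqn{P} (the magnitude of a negative water
#' potential). `b` is the tension (MPa) at which conductance has fallen to
#' \eqn{k_{max}/e}; `c` controls the steepness of the sigmoid. `b = Inf`
#' gives a constant-conductance (embolism-free) element, useful as a
#' limiting case.
#'
#' @param k_max maximal conductance (mol m-2 basal area s-1 MPa-1), > 0
#' @param b Weibull scale (MPa), > 0; may be `Inf`
#' @param c Weibull shape (dimensionless), > 0
#' @return an object of class `vulnerability_curve`
#' @export
#' @examples
#' vc <- vulnerability_curve(k_max = 10, b = 2, c = 2)
#' vulnerability_k(c(0, 1, 2), vc)
vulnerability_curve <- function(k_max, b, c) {
  stopifnot(is.numeric(k_max), length(k_max) == 1L, k_max > 0,
            is.numeric(b), length(b) == 1L, b > 0,
            is.numeric(c), length(c) == 1L, is.finite(c), c > 0)
  structure(list(k_max = k_max, b = b, c = c), class = "vulnerability_curve")
}

#' Evaluate a vulnerability curve
#'
#' @param tension xylem tension (MPa, >= 0); vectorised
#' @param curve a [vulnerability_curve()]
#' @return conductance at each tension
#' @export
vulnerability_k <- function(tension, curve) {
  stopifnot(inherits(curve, "vulnerability_curve"))
  if (any(tension < 0)) stop("tension must be non-negative (MPa)")
  if (is.infinite(curve$b)) return(rep_len(curve$k_max, length(tension)))
  curve$k_max * exp(-(tension / curve$b)^curve$c)
}

#' Soil hydraulic parameters (Campbell retention form)
#'
#' Unsaturated rhizosphere conductance follows the Campbell power law:
#' `k = k_sat` for tensions at or below the air-entry tension `psi_e`, and
#' `k_sat * (psi_e/psi)^(2 + 3/b_soil)` beyond it.
#'
#' @param k_sat saturated conductance (same basis as plant components); may be
#'   `NA` when the value is derived later from a network's resistance
#'   partitioning
#' @param psi_e air-entry tension (MPa), > 0
#' @param b_soil Campbell retention exponent, > 0
#' @return an object of class `soil_params`
#' @export
soil_params <- function(k_sat = NA_real_, psi_e = 0.002, b_soil = 4) {
  stopifnot(is.na(k_sat) || k_sat > 0, psi_e > 0, b_soil > 0)
  structure(list(k_sat = k_sat, psi_e = psi_e, b_soil = b_soil),
            class = "soil_params")
}

#' Unsaturated rhizosphere conductance
#'
#' @param psi soil/rhizosphere tension (MPa, >= 0); vectorised
#' @param soil a [soil_params()] with a finite `k_sat`
#' @return conductance at each tension
#' @export
rhizosphere_k <- function(psi, soil) {
  stopifnot(inherits(soil, "soil_params"), is.finite(soil$k_sat))
  if (any(psi < 0)) stop("tension must be non-negative (MPa)")
  eta <- 2 + 3 / soil$b_soil
  ifelse(psi <= soil$psi_e, soil$k_sat,
         soil$k_sat * (soil$psi_e / psi)^eta)
}

# ---- internal flux-integral interface ---------------------------------------
#
# Each series element exposes the cumulative flux integral
#   F(P) = integral_0^P k(x) dx,
# its inverse, and its capacity F(Inf). These are the primitives of the
# supply function: a component carrying steady flux E with inlet tension P_in
# has outlet tension  P_out = Finv(F(P_in) + E).
#
# For the Weibull curve F has a closed form through the lower incomplete
# gamma function:
#   F(P) = k_max (b/c) Gamma(1/c) pgamma((P/b)^c, 1/c)
# so both F and its inverse are exact (qgamma), with capacity
#   F(Inf) = k_max (b/c) Gamma(1/c).

hx_k    <- function(comp, P) UseMethod("hx_k")
hx_F    <- function(comp, P) UseMethod("hx_F")
hx_Finv <- function(comp, f) UseMethod("hx_Finv")
hx_cap  <- function(comp)    UseMethod("hx_cap")

#' @export
hx_k.vulnerability_curve <- function(comp, P) vulnerability_k(P, comp)

#' @export
hx_F.vulnerability_curve <- function(comp, P) {
  if (is.infinite(comp$b)) return(comp$k_max * P)
  a <- 1 / comp$c
  amp <- comp$k_max * (comp$b / comp$c) * gamma(a)
  amp * stats::pgamma((P / comp$b)^comp$c, a)
}

#' @export
hx_Finv.vulnerability_curve <- function(comp, f) {
  if (is.infinite(comp$b)) return(f / comp$k_max)
  a <- 1 / comp$c
  amp <- comp$k_max * (comp$b / comp$c) * gamma(a)
  out <- rep_len(Inf, length(f))
  ok <- f < amp
  out[ok] <- comp$b * stats::qgamma(f[ok] / amp, a)^(1 / comp$c)
  out
}

#' @export
hx_cap.vulnerability_curve <- function(comp) {
  if (is.infinite(comp$b)) return(Inf)
  comp$k_max * (comp$b / comp$c) * gamma(1 / comp$c)
}

#' @export
hx_k.soil_params <- function(comp, P) rhizosphere_k(P, comp)

#' @export
hx_F.soil_params <- function(comp, P) {
  eta <- 2 + 3 / comp$b_soil
  pe <- comp$psi_e
  below <- comp$k_sat * pmin(P, pe)
  above <- ifelse(P > pe,
                  comp$k_sat * pe^eta * (pe^(1 - eta) - P^(1 - eta)) / (eta - 1),
                  0)
  below + above
}

#' @export
hx_Finv.soil_params <- function(comp, f) {
  eta <- 2 + 3 / comp$b_soil
  pe <- comp$psi_e
  f_pe <- comp$k_sat * pe
  cap <- hx_cap(comp)
  out <- rep_len(Inf, length(f))
  lo <- f <= f_pe
  out[lo] <- f[lo] / comp$k_sat
  hi <- !lo & f < cap
  out[hi] <- (pe^(1 - eta) -
                (eta - 1) * (f[hi] - f_pe) / (comp$k_sat * pe^eta))^(1 / (1 - eta))
  out
}

#' @export
hx_cap.soil_params <- function(comp) {
  eta <- 2 + 3 / comp$b_soil
  comp$k_sat * comp$psi_e * (1 + 1 / (eta - 1))
}

# Constant-conductance rhizosphere element (saturated-soil default).
constant_element <- function(k) vulnerability_curve(k_max = k, b = Inf, c = 1)

# ---- flattened chain representation for the hot numerical paths -------------
#
# The S3 interface above is the public/reference surface; the supply-function
# solvers run thousands of chain evaluations inside root finders, so the
# per-element constants are precomputed once per network into plain lists and
# evaluated without dispatch. Both routes share the same closed forms.

build_chain_pack <- function(curves) {
  lapply(curves, function(comp) {
    if (inherits(comp, "soil_params")) {
      eta <- 2 + 3 / comp$b_soil
      list(type = 3L, k = comp$k_sat, pe = comp$psi_e, eta = eta,
           f_pe = comp$k_sat * comp$psi_e,
           cap = comp$k_sat * comp$psi_e * (1 + 1 / (eta - 1)))
    } else if (is.infinite(comp$b)) {
      list(type = 1L, k = comp$k_max, cap = Inf)
    } else {
      a <- 1 / comp$c
      list(type = 2L, k = comp$k_max, b = comp$b, c = comp$c, a = a,
           amp = comp$k_max * (comp$b / comp$c) * gamma(a),
           cap = comp$k_max * (comp$b / comp$c) * gamma(a))
    }
  })
}

pack_k <- function(el, P) {
  switch(el$type,
         rep_len(el$k, length(P)),
         el$k * exp(-(P / el$b)^el$c),
         ifelse(P <= el$pe, el$k, el$k * (el$pe / P)^el$eta))
}

pack_F <- function(el, P) {
  switch(el$type,
         el$k * P,
         el$amp * stats::pgamma((P / el$b)^el$c, el$a),
         el$k * pmin(P, el$pe) +
           ifelse(P > el$pe,
                  el$k * el$pe^el$eta * (el$pe^(1 - el$eta) - P^(1 - el$eta)) /
                    (el$eta - 1), 0))
}

pack_Finv <- function(el, f) {
  if (el$type == 1L) return(f / el$k)
  out <- rep_len(Inf, length(f))
  ok <- f < el$cap
  if (el$type == 2L) {
    out[ok] <- el$b * stats::qgamma(f[ok] / el$amp, el$a)^(1 / el$c)
  } else {
    lo <- ok & f <= el$f_pe
    out[lo] <- f[lo] / el$k
    hi <- ok & !lo
    out[hi] <- (el$pe^(1 - el$eta) -
                  (el$eta - 1) * (f[hi] - el$f_pe) /
                    (el$k * el$pe^el$eta))^(1 / (1 - el$eta))
  }
  out
}
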