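#' Plant hydraulic network for the SPA supply-demand model
#'
#' The soil-to-leaf continuum is represented as four series elements
#' (rhizosphere, root, stem, leaf). The whole-continuum maximal conductance
#' `k_total_max` is partitioned among elements by their fractional share of
#' total resistance at maximum conductance, so each element's maximal
#' conductance is `k_total_max / fraction`. Root, stem and leaf decline with
#' tension along Weibull vulnerability curves; the rhizosphere is either a
#' constant saturated element (default, appropriate when the soil is kept at
#' or near saturation) or a Campbell unsaturated element.
#'
#' @param k_total_max whole-continuum maximal conductance
#'   (mol m-2 basal area s-1 MPa-1), > 0
#' @param G_max maximal canopy vapour conductance (kg hr-1 m-2 basal area per
#'   unit mole-fraction VPD), > 0
#' @param resistance_fractions named fractions of total resistance at maximum
#'   conductance for `rhizosphere`, `root`, `stem`, `leaf`; each in (0,1),
#'   summing to 1
#' @param weibull_b named Weibull scales (MPa) for `root`, `stem`, `leaf`
#' @param weibull_c named Weibull shapes for `root`, `stem`, `leaf`
#' @param soil a [soil_params()]; its `k_sat` is derived from the rhizosphere
#'   resistance fraction and may be left `NA`
#' @param rhizosphere_mode `"constant"` (saturated Darcy element) or
#'   `"campbell"` (unsaturated power-law decline)
#' @return an object of class `plant_network`
#' @export
#' @examples
#' net <- plant_network(k_total_max = 3.96, G_max = 8000)
#' net
plant_network <- function(k_total_max, G_max,
                          resistance_fractions = c(rhizosphere = 0.05,
                                                   root = 0.35,
                                                   stem = 0.30,
                                                   leaf = 0.30),
                          weibull_b = c(root = 3.0, stem = 3.0, leaf = 3.0),
                          weibull_c = c(root = 2.5, stem = 2.5, leaf = 2.5),
                          soil = soil_params(),
                          rhizosphere_mode = c("constant", "campbell")) {
  rhizosphere_mode <- match.arg(rhizosphere_mode)
  comp_names <- c("rhizosphere", "root", "stem", "leaf")
  stopifnot(k_total_max > 0, G_max > 0,
            setequal(names(resistance_fractions), comp_names),
            all(resistance_fractions > 0), all(resistance_fractions < 1),
            abs(sum(resistance_fractions) - 1) < 1e-9,
            setequal(names(weibull_b), c("root", "stem", "leaf")),
            setequal(names(weibull_c), c("root", "stem", "leaf")))
  fr <- resistance_fractions[comp_names]

  k_sat <- k_total_max / fr[["rhizosphere"]]
  rhizo <- if (rhizosphere_mode == "constant") {
    constant_element(k_sat)
  } else {
    soil_params(k_sat = k_sat, psi_e = soil$psi_e, b_soil = soil$b_soil)
  }
  curves <- list(rhizosphere = rhizo)
  for (nm in c("root", "stem", "leaf")) {
    curves[[nm]] <- vulnerability_curve(k_max = k_total_max / fr[[nm]],
                                        b = weibull_b[[nm]], c = weibull_c[[nm]])
  }
  structure(list(k_total_max = k_total_max,
                 G_max = G_max,
                 resistance_fractions = fr,
                 b = weibull_b[c("root", "stem", "leaf")],
                 c = weibull_c[c("root", "stem", "leaf")],
                 soil = soil,
                 rhizosphere_mode = rhizosphere_mode,
                 curves = curves,
                 pack = build_chain_pack(curves)),
            class = "plant_network")
}

#' @export
print.plant_network <- function(x, ...) {
  cat("<plant_network>\n")
  cat(sprintf("  k_total_max: %.4g mol m-2 s-1 MPa-1\n", x$k_total_max))
  cat(sprintf("  G_max:       %.4g kg hr-1 m-2 (per mole fraction VPD)\n", x$G_max))
  cat(sprintf("  resistance:  %s\n",
              paste(sprintf("%s %.3g", names(x$resistance_fractions),
                            x$resistance_fractions), collapse = ", ")))
  cat(sprintf("  rhizosphere: %s\n", x$rhizosphere_mode))
  invisible(x)
}

# Rebuild a network with some top-level parameters replaced.
network_with <- function(net, k_total_max = net$k_total_max,
                         G_max = net$G_max,
                         resistance_fractions = net$resistance_fractions,
                         b = net$b, c = net$c) {
  plant_network(k_total_max = k_total_max, G_max = G_max,
                resistance_fractions = resistance_fractions,
                weibull_b = b, weibull_c = c, soil = net$soil,
                rhizosphere_mode = net$rhizosphere_mode)
}

#' Apply a flood-impairment scale to a hydraulic network
#'
#' With `target = "whole_plant"` the whole-continuum maximal conductance is
#' multiplied by `scale`, every element scaling proportionally (resistance
#' partitioning unchanged). With `target = "root_component"` only the root
#' element's maximal conductance is scaled; the whole-plant maximum and the
#' resistance fractions are recomputed from the series identity, so the new
#' `k_total_max` is `k_total_max / ((1 - f_root) + f_root/scale)`.
#'
#' @param net a [plant_network()]
#' @param scale impairment fraction in (0, 1]
#' @param target `"whole_plant"` or `"root_component"`
#' @return a new `plant_network`; the input is not modified
#' @export
apply_flood <- function(net, scale, target = c("whole_plant", "root_component")) {
  target <- match.arg(target)
  stopifnot(inherits(net, "plant_network"))
  if (!is.finite(scale) || scale <= 0) stop("scale must be in (0, 1]")
  if (scale > 1) stop("scale must be in (0, 1]")
  if (scale == 1) return(net)
  if (target == "whole_plant") {
    network_with(net, k_total_max = net$k_total_max * scale)
  } else {
    fr <- net$resistance_fractions
    f_root <- fr[["root"]]
    new_ktot <- net$k_total_max / ((1 - f_root) + f_root / scale)
    # resistances: root share grows by 1/scale, others unchanged
    res <- fr / net$k_total_max
    res[["root"]] <- res[["root"]] / scale
    network_with(net, k_total_max = new_ktot,
                 resistance_fractions = res / sum(res))
  }
}

# Ordered series elements, rhizosphere first.
network_elements <- function(net) net$curves
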