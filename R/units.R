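# Unit constants shared across the package.
#
# Hydraulic conductances are carried in mol m-2 (basal area) s-1 MPa-1; the
# canopy conductance G and transpiration flux E cross into the kg-per-hour
# basis used for greenhouse-scale reporting at the regulation step.

# kg of water per hour carried by 1 mol s-1 (18.015 g mol-1 * 3600 s / 1000)
KG_HR_PER_MOL_S <- 18.015 * 3600 / 1000

# Atmospheric pressure (kPa) used to convert VPD to a mole fraction.
ATM_KPA <- 101.3

#' Convert a molar water flux to the kg-per-hour basis
#'
#' @param e_mol flux in mol m-2 s-1
#' @return flux in kg m-2 hr-1
#' @keywords internal
mol_s_to_kg_hr <- function(e_mol) e_mol * KG_HR_PER_MOL_S

#' @rdname mol_s_to_kg_hr
#' @param e_kg flux in kg m-2 hr-1
#' @keywords internal
kg_hr_to_mol_s <- function(e_kg) e_kg / KG_HR_PER_MOL_S

#' Convert vapour pressure deficit to a mole fraction
#'
#' @param vpd_kpa vapour pressure deficit (kPa)
#' @return dimensionless mole-fraction demand
#' @keywords internal
vpd_mole_fraction <- function(vpd_kpa) vpd_kpa / ATM_KPA
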