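#' @useDynLib lipogate, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx density dnorm lm median optim quantile rbinom
#'   rexp rgamma rnorm runif sd setNames rchisq pt qt nls coef resid var
#'   predict complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

# Gas constant, kJ mol^-1 K^-1 (CODATA).  Thermal energy kT is always
# expressed per mole so that it combines directly with biasing force
# constants quoted in kJ mol^-1 nm^-2.
.R_GAS <- 0.008314462618

#' Thermal energy in kJ/mol
#'
#' @param temperature Temperature in kelvin. The default matches the
#'   thermostat setting used throughout the simulation stages.
#' @return Thermal energy \eqn{k_B T} in kJ/mol.
#' @export
kBT <- function(temperature = 303.15) .R_GAS * temperature

#' Transmembrane potential from a uniform applied field
#'
#' A static external electric field applied along the membrane normal of a
#' periodic simulation cell produces a potential difference across the box
#' equal to field strength times box length.
#'
#' @param field_V_per_nm Field strength in V/nm.
#' @param box_length_nm Box length along the field direction, nm.
#' @return Potential difference in mV.
#' @examples
#' transmembrane_potential(0.05, 8.4) # 420 mV
#' @export
transmembrane_potential <- function(field_V_per_nm, box_length_nm) {
  stopifnot(is.finite(field_V_per_nm), box_length_nm > 0)
  field_V_per_nm * box_length_nm * 1000
}

#' Ion concentrations after diluting a liposome aliquot into assay buffer
#'
#' Computes the final monovalent cation composition when a small volume of
#' liposome suspension (prepared in KCl inside-buffer) is diluted into a
#' NaCl outside-buffer, as done when setting up a fluorimetric flux assay.
#'
#' @param vol_aliquot_ul Aliquot volume, microlitres.
#' @param conc_inside_mM Salt concentration of the aliquot buffer, mM (KCl).
#' @param vol_final_ul Final assay volume, microlitres.
#' @param conc_outside_mM Salt concentration of the dilution buffer, mM (NaCl).
#' @return Named vector with final `K` and `Na` concentrations in mM.
#' @examples
#' dilution_concentrations(5, 150, 110, 150) # K 6.8 mM, Na 143.2 mM
#' @export
dilution_concentrations <- function(vol_aliquot_ul, conc_inside_mM,
                                    vol_final_ul, conc_outside_mM) {
  stopifnot(vol_final_ul >= vol_aliquot_ul, vol_aliquot_ul >= 0)
  k <- vol_aliquot_ul * conc_inside_mM / vol_final_ul
  na <- (vol_final_ul - vol_aliquot_ul) * conc_outside_mM / vol_final_ul
  c(K = k, Na = na)
}

# Bondi-style van der Waals radii (angstrom); unknown elements fall back to
# the generic carbon-like default below, as documented in read_structure().
.VDW_TABLE <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  "F" = 1.47, CL = 1.75, BR = 1.85, "I" = 1.98,
  K = 2.75, "NA" = 2.27, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 2.00
)
.VDW_DEFAULT <- 1.70

# Atomic masses (g/mol) for mass-weighted centres of mass.
.MASS_TABLE <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  K = 39.098, "NA" = 22.990, CL = 35.45, MG = 24.305, CA = 40.078
)
.MASS_DEFAULT <- 12.011

#' Van der Waals radius lookup
#'
#' @param element Character vector of element symbols.
#' @param overrides Optional named numeric vector of per-element overrides.
#' @return Numeric vector of radii in angstrom.
#' @export
vdw_radius <- function(element, overrides = NULL) {
  tab <- .VDW_TABLE
  if (!is.null(overrides)) tab[toupper(names(overrides))] <- overrides
  r <- unname(tab[toupper(element)])
  r[is.na(r)] <- .VDW_DEFAULT
  r
}

atomic_mass <- function(element) {
  m <- unname(.MASS_TABLE[toupper(element)])
  m[is.na(m)] <- .MASS_DEFAULT
  m
}
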