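#' Gas constant in J/(mol K)
#' @keywords internal
.R_GAS <- 8.314

#' Convert Celsius to Kelvin
#'
#' @param temp_C temperature(s) in degrees Celsius.
#' @return temperature(s) in Kelvin.
#' @export
celsius_to_kelvin <- function(temp_C) temp_C + 273.15

#' Convert Kelvin to Celsius
#'
#' @param temp_K temperature(s) in Kelvin.
#' @return temperature(s) in degrees Celsius.
#' @export
kelvin_to_celsius <- function(temp_K) temp_K - 273.15

#' Protein or chromophore concentration from absorbance (Beer-Lambert)
#'
#' Computes molar concentration c = A / (epsilon * l). Typical extinction
#' coefficients for a luciferase assay are 12,400 M^-1 cm^-1 at 445 nm for
#' flavin mononucleotide and 80,000 M^-1 cm^-1 at 280 nm for the enzyme.
#'
#' @param A measured absorbance (dimensionless, >= 0).
#' @param epsilon molar extinction coefficient, M^-1 cm^-1 (> 0).
#' @param path_cm optical path length in cm (> 0, default 1).
#' @return concentration in mol/L.
#' @examples
#' concentration_from_absorbance(0.124, 12400)  # 1e-5 M = 10 uM
#' @export
concentration_from_absorbance <- function(A, epsilon, path_cm = 1) {
  if (any(A < 0)) stop("absorbance must be non-negative")
  if (epsilon <= 0) stop("extinction coefficient must be positive")
  if (path_cm <= 0) stop("path length must be positive")
  A / (epsilon * path_cm)
}

#' Molarity of a sucrose solution from its weight fraction
#'
#' c = w * rho * 1000 / M with solution density rho in g/mL and sucrose molar
#' mass M = 342.30 g/mol. The default density 1.127 g/mL (20 C literature
#' value for ~30 wt%) makes a 30 w/w% solution 0.99 M.
#'
#' @param wt_fraction mass fraction of sucrose, in [0, 1).
#' @param density_g_per_mL solution density in g/mL.
#' @param molar_mass sucrose molar mass in g/mol.
#' @return concentration in mol/L.
#' @examples
#' sucrose_molarity(0.30)  # ~0.99 M
#' @export
sucrose_molarity <- function(wt_fraction, density_g_per_mL = 1.127,
                             molar_mass = 342.30) {
  if (wt_fraction < 0 || wt_fraction >= 1)
    stop("weight fraction must lie in [0, 1)")
  if (density_g_per_mL <= 0 || molar_mass <= 0)
    stop("density and molar mass must be positive")
  wt_fraction * density_g_per_mL * 1000 / molar_mass
}
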