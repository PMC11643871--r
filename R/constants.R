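# Physical constants and element tables used across the package.
# All masses in Da, radii in Angstrom, energies in kcal/mol unless stated.

# CODATA-2018
.kB <- 1.380649e-23      # J/K
.h  <- 6.62607015e-34    # J s
.R_kcal <- 1.987e-3      # kcal mol^-1 K^-1, conventional value used in
                         # coalescence bracket equations
.m_electron <- 0.000548579909  # Da

.hartree_kcal <- 627.5095  # kcal/mol per hartree

# IUPAC conventional (abridged) standard atomic weights.
.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
  Br = 79.904, I = 126.904
)

# Principal (most abundant) isotope masses.
.monoisotopic_masses <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  F = 18.99840322, Na = 22.9897692809, P = 30.97376163, S = 31.97207100,
  Cl = 34.96885268, K = 38.96370668, Br = 78.9183371, I = 126.904473
)

# Isotope mass/abundance tables for the polyisotopic heavy elements expanded
# by isotope_pattern().  Abundances are IUPAC representative values.
.isotope_tables <- list(
  Cl = data.frame(mass = c(34.96885268, 36.96590259),
                  abundance = c(0.7576, 0.2424)),
  S  = data.frame(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
                  abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Br = data.frame(mass = c(78.9183371, 80.9162906),
                  abundance = c(0.5069, 0.4931))
)

# van der Waals radii.  H, O and S carry the values conventionally used in
# carbohydrate contact analysis (H 1.17, O 1.52, S 1.80); the rest are Bondi.
.default_vdw <- data.frame(
  element = c("H", "O", "S", "C", "N", "F", "Cl", "Na", "P", "Br", "I"),
  radius  = c(1.17, 1.52, 1.80, 1.70, 1.55, 1.47, 1.75, 2.27, 1.80, 1.85, 1.98),
  source  = c("contact-analysis", "contact-analysis", "contact-analysis",
              rep("Bondi", 8)),
  stringsAsFactors = FALSE
)

#' Physical constants used by the package
#'
#' Returns the pinned values of the physical constants the package computes
#' with: the Boltzmann constant, the Planck constant, the gas constant in
#' kcal/(mol K), the hartree-to-kcal/mol conversion, and the electron mass in
#' Da.  Having them in one place makes every derived quantity auditable.
#'
#' @return Named list of constants.
#' @export
#' @examples
#' physical_constants()$R_kcal
physical_constants <- function() {
  list(kB = .kB, h = .h, R_kcal = .R_kcal,
       hartree_kcal = .hartree_kcal, m_electron = .m_electron)
}

#' Default van der Waals radii table
#'
#' The table used by [vdw_contact()].  Hydrogen, oxygen and sulfur carry the
#' radii conventionally used in carbohydrate close-contact analysis
#' (1.17, 1.52 and 1.80 A, so that r(H) + r(O) = 2.69 A and
#' r(H) + r(S) = 2.97 A); the remaining elements use Bondi radii.  Users can
#' pass a modified copy to [vdw_contact()] to override any value.
#'
#' @return A data frame with columns `element`, `radius` (Angstrom), `source`.
#' @export
#' @examples
#' vdw_radii()
vdw_radii <- function() .default_vdw

#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (round-half-up for
#' positive numbers), matching the typography of elemental-analysis and
#' high-resolution m/z reports.  Base R's [round()] rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.675, 2)   # 2.68
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
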