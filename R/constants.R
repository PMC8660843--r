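#' Physical constants used throughout the package
#'
#' CODATA 2018 values, centralized so that every unit conversion in the
#' package (Coulomb couplings in cm^-1, Marcus rates in s^-1) is assembled
#' from a single table.
#'
#' @format A named list:
#' \describe{
#'   \item{h}{Planck constant, J s (exact)}
#'   \item{hbar}{reduced Planck constant, J s}
#'   \item{c}{speed of light, m s^-1 (exact)}
#'   \item{kB}{Boltzmann constant, J K^-1 (exact)}
#'   \item{e}{elementary charge, C (exact)}
#'   \item{eps0}{vacuum permittivity, F m^-1}
#'   \item{bohrA}{Bohr radius, Angstrom}
#'   \item{hartreeJ}{Hartree energy, J}
#'   \item{hartreeCm1}{Hartree energy, cm^-1}
#'   \item{coulombCm1}{e^2/Angstrom expressed in cm^-1: the conversion
#'     constant of the transition-charge Coulomb sum, assembled as
#'     (Hartree in cm^-1) x (Bohr radius in Angstrom)}
#'   \item{cm1ToJ}{1 cm^-1 in J}
#'   \item{eVToJ}{1 eV in J}
#' }
#' @export
physicalConstants <- local({
  h <- 6.62607015e-34
  c <- 299792458
  kB <- 1.380649e-23
  e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  bohrA <- 0.529177210903
  hartreeJ <- 4.3597447222071e-18
  hartreeCm1 <- hartreeJ / (h * c * 100)
  list(
    h = h, hbar = h / (2 * pi), c = c, kB = kB, e = e, eps0 = eps0,
    bohrA = bohrA, hartreeJ = hartreeJ, hartreeCm1 = hartreeCm1,
    coulombCm1 = hartreeCm1 * bohrA,
    cm1ToJ = h * c * 100, eVToJ = e
  )
})

#' Bondi van der Waals radii (Angstrom) by element symbol
#'
#' Used by the rigid-sphere overlap parameter; elements not listed fall back
#' to the carbon radius.
#' @export
bondiRadii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Mg = 1.73, Br = 1.85, I = 1.98
)
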