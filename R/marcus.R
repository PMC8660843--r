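#' Marcus-theory charge-transfer rate
#'
#' Classical (high-temperature) Marcus rate for nonadiabatic electron
#' transfer between a carotenoid and a chlorophyll,
#' \deqn{k = \frac{2\pi}{\hbar} |V|^2 (4\pi\lambda k_B T)^{-1/2}
#'       \exp\!\left(-\frac{(\Delta G + \lambda)^2}{4\lambda k_B T}\right)}
#' with the electronic coupling V supplied in cm^-1, the driving force
#' \eqn{\Delta G} and reorganization energy \eqn{\lambda} in eV, and the
#' temperature in K. All unit conversions use the centralized CODATA table.
#' At the barrierless point \eqn{\Delta G = -\lambda} the exponential factor
#' is 1 and k equals the prefactor; in the normal region
#' (\eqn{\Delta G > -\lambda}) k decreases with increasing \eqn{\Delta G}.
#' The energetics (CT-state energies, reorganization energies) come from
#' external quantum-chemistry tables; this function only turns them into
#' rates.
#'
#' Vectorized over all arguments.
#'
#' @param vCm1 electronic coupling, cm^-1.
#' @param dGeV driving force Delta G, eV.
#' @param lambdaEV reorganization energy lambda, eV (> 0).
#' @param temperatureK temperature, K (> 0, default 300).
#' @return data.frame with columns \code{k} (s^-1) and \code{activation},
#'   the dimensionless activation term (Delta G + lambda)^2 / (4 lambda kB T).
#' @export
marcusRate <- function(vCm1, dGeV, lambdaEV, temperatureK = 300) {
  if (any(lambdaEV <= 0)) stop("reorganization energy must be positive")
  if (any(temperatureK <= 0)) stop("temperature must be positive")
  pc <- physicalConstants
  V <- abs(vCm1) * pc$cm1ToJ
  lam <- lambdaEV * pc$eVToJ
  dG <- dGeV * pc$eVToJ
  kT <- pc$kB * temperatureK
  act <- (dG + lam)^2 / (4 * lam * kT)
  k <- (2 * pi / pc$hbar) * V^2 / sqrt(4 * pi * lam * kT) * exp(-act)
  data.frame(k = k, activation = act)
}

#' Is a charge-transfer quenching channel kinetically active?
#'
#' A CT channel is called active when its Marcus rate is at least
#' \code{thresholdRatio} times the competing decay rate of the donor state
#' (boundary inclusive). With the default ratio of 1 this asks whether
#' electron transfer can outcompete the other deactivation pathways.
#'
#' @param k CT rate(s), s^-1.
#' @param competingRate competing decay rate(s), s^-1.
#' @param thresholdRatio activity threshold (default 1).
#' @return character vector "active"/"inactive".
#' @export
channelActivity <- function(k, competingRate, thresholdRatio = 1) {
  if (any(k < 0) || any(competingRate < 0)) stop("rates must be >= 0")
  ifelse(k >= thresholdRatio * competingRate, "active", "inactive")
}
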