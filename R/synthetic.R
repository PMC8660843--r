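#' Specification of a synthetic multi-basin ensemble
#'
#' Defines the study conditions for the synthetic-data generator: a
#' polyalanine-like two-helix scaffold whose planted backbone dihedrals are
#' drawn per frame from per-cluster von Mises (circular unimodal)
#' distributions, emulating the multi-basin dihedral landscape of a
#' pigment-protein complex. Everything else about the scaffold is rigid up
#' to a small wrapped-Gaussian jitter.
#'
#' @param nFrames number of frames (>= 1).
#' @param nResidues scaffold length (default 20).
#' @param clusterWeights probability vector over planted clusters; must sum
#'   to 1.
#' @param plantedResidues residue numbers whose phi dihedral carries the
#'   planted signal (must be >= 2, phi is undefined at the N-terminus).
#' @param plantedMeans matrix nClusters x length(plantedResidues) of
#'   circular means, radians.
#' @param concentration von Mises concentration(s), recycled to the shape of
#'   \code{plantedMeans}; > 0, \code{Inf} means a degenerate (noise-free)
#'   distribution.
#' @param seed integer seed threaded through all stochastic draws.
#' @param noiseLevel sd (radians) of the Gaussian jitter applied to all
#'   non-planted dihedrals.
#' @return list of class "EnsembleSpec".
#' @export
ensembleSpec <- function(nFrames, nResidues = 20, clusterWeights = 1,
                         plantedResidues = integer(0), plantedMeans = NULL,
                         concentration = 50, seed = 1, noiseLevel = 0.05) {
  if (nFrames < 1) stop("nFrames must be >= 1")
  if (abs(sum(clusterWeights) - 1) > 1e-12)
    stop("clusterWeights must sum to 1")
  if (any(clusterWeights < 0)) stop("clusterWeights must be non-negative")
  K <- length(clusterWeights)
  P <- length(plantedResidues)
  if (P > 0) {
    if (any(plantedResidues < 2) || any(plantedResidues > nResidues))
      stop("plantedResidues must lie in 2..nResidues")
    plantedMeans <- matrix(plantedMeans, K, P)
  } else {
    plantedMeans <- matrix(numeric(0), K, 0)
  }
  conc <- matrix(concentration, K, max(P, 1))[, seq_len(P), drop = FALSE]
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (noiseLevel < 0) stop("noiseLevel must be >= 0")
  structure(list(nFrames = as.integer(nFrames),
                 nResidues = as.integer(nResidues),
                 clusterWeights = clusterWeights,
                 plantedResidues = as.integer(plantedResidues),
                 plantedMeans = plantedMeans,
                 concentration = conc,
                 seed = as.integer(seed),
                 noiseLevel = noiseLevel),
            class = "EnsembleSpec")
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution;
# deterministic under set.seed. kappa = Inf returns the mean exactly.
rVonMises <- function(n, mu, kappa) {
  if (!is.finite(kappa)) return(rep(wrapAngle(mu), n))
  if (kappa < 1e-8) return(wrapAngle(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
      i <- i + 1L
    }
  }
  wrapAngle(out)
}

# idealized backbone geometry (Angstrom / radians); dihedrals are the only
# degrees of freedom of the scaffold
.bb <- list(
  bNCA = 1.458, bCAC = 1.525, bCN = 1.329, bCO = 1.231,
  bCACB = 1.530, bCBCG = 1.520,
  aNCAC = 111.0 * pi / 180, aCACN = 116.6 * pi / 180,
  aCNCA = 121.7 * pi / 180, aCACO = 120.5 * pi / 180,
  aNCACB = 110.5 * pi / 180, aCACBCG = 114.0 * pi / 180,
  omega = pi, cbTorsion = -122 * pi / 180
)

# build one frame of the scaffold from per-residue dihedrals (radians);
# atoms per residue: N, CA, C, O, CB, CG
buildScaffoldFrame <- function(phi, psi, chi1) {
  n <- length(phi)
  g <- .bb
  xyz <- matrix(NA_real_, 6 * n, 3)
  at <- function(i, a) 6 * (i - 1) + a       # a: 1 N, 2 CA, 3 C, 4 O, 5 CB, 6 CG
  xyz[at(1, 1), ] <- c(0, 0, 0)
  xyz[at(1, 2), ] <- c(g$bNCA, 0, 0)
  xyz[at(1, 3), ] <- xyz[at(1, 2), ] +
    g$bCAC * c(-cos(g$aNCAC), sin(g$aNCAC), 0)
  for (i in seq_len(n)) {
    N <- xyz[at(i, 1), ]; CA <- xyz[at(i, 2), ]; C <- xyz[at(i, 3), ]
    if (i < n) {
      Nn <- placeAtom(N, CA, C, g$bCN, g$aCACN, psi[i])
      CAn <- placeAtom(CA, C, Nn, g$bNCA, g$aCNCA, g$omega)
      Cn <- placeAtom(C, Nn, CAn, g$bCAC, g$aNCAC, phi[i + 1])
      xyz[at(i + 1, 1), ] <- Nn
      xyz[at(i + 1, 2), ] <- CAn
      xyz[at(i + 1, 3), ] <- Cn
    }
    xyz[at(i, 4), ] <- placeAtom(N, CA, C, g$bCO, g$aCACO, psi[i] - pi)
    CB <- placeAtom(C, N, CA, g$bCACB, g$aNCACB, g$cbTorsion)
    xyz[at(i, 5), ] <- CB
    xyz[at(i, 6), ] <- placeAtom(N, CA, CB, g$bCBCG, g$aCACBCG, chi1[i])
  }
  xyz
}

scaffoldTopology <- function(nResidues) {
  elety <- c("N", "CA", "C", "O", "CB", "CG")
  elesy <- c("N", "C", "C", "O", "C", "C")
  data.frame(
    chain = "A",
    resid = "UNK",
    resno = rep(seq_len(nResidues), each = 6),
    elety = rep(elety, nResidues),
    elesy = rep(elesy, nResidues),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic multi-basin ensemble with planted ground truth
#'
#' Draws one cluster label per frame from the spec's weights, then draws the
#' planted phi dihedrals from that cluster's von Mises distributions and
#' rebuilds Cartesian coordinates analytically from the idealized two-helix
#' scaffold (fixed bond lengths and angles; dihedrals are the only degrees
#' of freedom, so the planted circular basins are exactly realized in the
#' coordinates). Reproducible: the same spec and seed give bitwise-identical
#' output.
#'
#' @param spec an \code{\link{ensembleSpec}}.
#' @return list with \code{ensemble} (a
#'   \linkS4class{ConformationalEnsemble}) and \code{truth} (list with
#'   0-based \code{labels} and the planted means).
#' @export
generateEnsemble <- function(spec) {
  stopifnot(inherits(spec, "EnsembleSpec"))
  set.seed(spec$seed)
  n <- spec$nResidues
  K <- length(spec$clusterWeights)
  nf <- spec$nFrames
  labels <- sample.int(K, nf, replace = TRUE, prob = spec$clusterWeights)
  # default scaffold dihedrals: two alpha-helices joined by a short loop
  phi0 <- rep(-57, n); psi0 <- rep(-47, n); chi0 <- rep(-60, n)
  loop <- (floor(n / 2)):(min(n, floor(n / 2) + 2))
  phi0[loop] <- -120; psi0[loop] <- 130
  phi0 <- phi0 * pi / 180; psi0 <- psi0 * pi / 180; chi0 <- chi0 * pi / 180
  P <- length(spec$plantedResidues)
  coords <- array(NA_real_, c(nf, 6 * n, 3))
  for (f in seq_len(nf)) {
    k <- labels[f]
    phi <- phi0; psi <- psi0; chi1 <- chi0
    if (spec$noiseLevel > 0) {
      phi <- wrapAngle(phi + stats::rnorm(n, 0, spec$noiseLevel))
      psi <- wrapAngle(psi + stats::rnorm(n, 0, spec$noiseLevel))
      chi1 <- wrapAngle(chi1 + stats::rnorm(n, 0, spec$noiseLevel))
    }
    for (p in seq_len(P)) {
      phi[spec$plantedResidues[p]] <-
        rVonMises(1, spec$plantedMeans[k, p], spec$concentration[k, p])
    }
    coords[f, , ] <- buildScaffoldFrame(phi, psi, chi1)
  }
  ens <- ConformationalEnsemble(
    coords, scaffoldTopology(n),
    metadata = list(generator = "generateEnsemble", seed = spec$seed,
                    spec = spec))
  list(ensemble = ens,
       truth = list(labels = labels - 1L,
                    plantedResidues = spec$plantedResidues,
                    plantedMeans = spec$plantedMeans))
}

#' Write planted truth labels as TSV
#' @param truth the truth component returned by \code{generateEnsemble}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTruthLabels <- function(truth, path) {
  writeTSV(data.frame(frame_index = seq_along(truth$labels),
                      cluster_label = truth$labels), path)
}

#' Generate a rigid toy pigment pair with transition charges
#'
#' Two identical planar six-atom pigments carrying charge-neutral
#' transition-charge patterns with a nonzero transition dipole (charges
#' -q on one edge, +q on the other). Pigment A lies in the z = 0 plane;
#' pigment B is rotated about z by \code{rotation} degrees and displaced
#' along z by exactly \code{separation} Angstrom. A fixture for coupling
#' and overlap analyses with analytically known limits (point-dipole
#' behaviour at large separation, zero overlap beyond sphere contact).
#'
#' @param separation centre-to-centre separation along z, Angstrom (> 0).
#' @param rotation in-plane rotation of pigment B, degrees.
#' @param chargeMagnitude |q| of the edge charges, e (default 0.1).
#' @return list with \code{A}, \code{B} (\linkS4class{PigmentChargeSet}
#'   with coordinates) and \code{geometry}.
#' @export
generatePigmentPair <- function(separation, rotation = 0,
                                chargeMagnitude = 0.1) {
  if (separation <= 0) stop("separation must be positive")
  base <- cbind(x = c(-1.4, -1.4, 0, 0, 1.4, 1.4),
                y = c(-0.7, 0.7, -0.7, 0.7, -0.7, 0.7),
                z = rep(0, 6))
  q <- chargeMagnitude * c(-1, -1, 0, 0, 1, 1)
  th <- rotation * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  coordsB <- base %*% t(R)
  coordsB[, 3] <- coordsB[, 3] + separation
  nm <- paste0("C", 1:6)
  mk <- function(id, xyz) new("PigmentChargeSet", pigmentId = id,
                              transition = "toy", atomNames = nm,
                              charges = q, coords = xyz)
  list(A = mk("toyA", base), B = mk("toyB", coordsB),
       geometry = list(separation = separation, rotation = rotation))
}

#' Generate a toy conjugated chain flipping between s-cis and s-trans
#'
#' A rigid eight-carbon chain whose first dihedral d1 is drawn near 0
#' degrees (s-cis) with probability \code{sCisFraction} and near 180
#' degrees (s-trans) otherwise, with tight von Mises noise (concentration
#' 200, circular sd about 4 degrees) emulating the pedaling flip of a
#' carotenoid's terminal conjugated dihedral. All other chain dihedrals
#' stay s-trans. The realized conformer of every frame is recorded in the
#' ensemble metadata.
#'
#' @param nFrames number of frames.
#' @param sCisFraction planted probability of the s-cis conformer, in
#'   [0, 1].
#' @param seed integer seed.
#' @param concentration von Mises concentration of the dihedral noise.
#' @return a \linkS4class{ConformationalEnsemble} (chain "X", residue LUT,
#'   atoms C1..C8) with metadata \code{sCisFraction}, \code{conformer}.
#' @export
generateConjugatedChainSeries <- function(nFrames, sCisFraction, seed = 1,
                                          concentration = 200) {
  if (sCisFraction < 0 || sCisFraction > 1)
    stop("sCisFraction must be in [0, 1]")
  set.seed(seed)
  nAt <- 8L
  cis <- stats::runif(nFrames) < sCisFraction
  coords <- array(NA_real_, c(nFrames, nAt, 3))
  bond <- 1.45; ang <- 120 * pi / 180
  for (f in seq_len(nFrames)) {
    tors <- rVonMises(nAt - 3L, pi, concentration)
    tors[1] <- rVonMises(1, if (cis[f]) 0 else pi, concentration)
    xyz <- matrix(NA_real_, nAt, 3)
    xyz[1, ] <- c(0, 0, 0)
    xyz[2, ] <- c(bond, 0, 0)
    xyz[3, ] <- xyz[2, ] + bond * c(-cos(ang), sin(ang), 0)
    for (i in 4:nAt) {
      xyz[i, ] <- placeAtom(xyz[i - 3, ], xyz[i - 2, ], xyz[i - 1, ],
                            bond, ang, tors[i - 3])
    }
    coords[f, , ] <- xyz
  }
  top <- data.frame(chain = "X", resid = "LUT", resno = 1L,
                    elety = paste0("C", seq_len(nAt)),
                    elesy = "C", stringsAsFactors = FALSE)
  ConformationalEnsemble(
    coords, top,
    metadata = list(generator = "generateConjugatedChainSeries",
                    seed = seed, sCisFraction = sCisFraction,
                    conformer = ifelse(cis, "s-cis", "s-trans")))
}
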