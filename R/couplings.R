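#' Coulomb coupling between two transition-charge distributions
#'
#' The electronic coupling between two pigment transitions in the
#' transition-charge (TrESP) approximation: the Coulomb interaction of the
#' two sets of atomic transition charges,
#' \deqn{V = K \sum_{i \in A} \sum_{j \in B} q_i q_j / r_{ij}}
#' with charges in elementary-charge units, distances in Angstrom and K the
#' CODATA-assembled constant converting e^2/Angstrom to cm^-1 (see
#' \code{physicalConstants$coulombCm1}). The sum is evaluated without any
#' distance cutoff. V is symmetric under swapping the pigments.
#'
#' @param coordsA,coordsB numeric matrices n x 3 (Angstrom).
#' @param chargesA,chargesB numeric vectors (e), one charge per atom.
#' @return the coupling in cm^-1.
#' @export
coulombCoupling <- function(coordsA, chargesA, coordsB, chargesB) {
  if (length(chargesA) != nrow(coordsA) || length(chargesB) != nrow(coordsB))
    stop("one charge per atom required")
  D <- interatomicDistances(coordsA, coordsB)
  if (any(D < 1e-9))
    stop("coincident atoms across the two sets (r = 0)")
  physicalConstants$coulombCm1 *
    drop(chargesA %*% (1 / D) %*% chargesB)
}

# pairwise distance matrix between two coordinate sets (rows x rows)
interatomicDistances <- function(A, B) {
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(D2, 0))
}

#' Rigid-sphere model for the overlap parameter
#'
#' Atom-centred spheres with Bondi van der Waals radii scaled by a single
#' global factor; the scale factor is the one free parameter of the
#' geometric overlap proxy.
#'
#' @param scale global scale factor applied to all radii (default 1).
#' @param radii named radius table (Angstrom) overriding
#'   \code{\link{bondiRadii}}.
#' @return list of class "SphereModel" with elements \code{radii},
#'   \code{scale}.
#' @export
sphereModel <- function(scale = 1, radii = bondiRadii) {
  if (any(radii <= 0) || scale <= 0) stop("radii and scale must be positive")
  structure(list(radii = radii, scale = scale), class = "SphereModel")
}

# radius per atom from element symbols; unknown elements fall back to C
sphereRadiiFor <- function(elements, model) {
  r <- model$radii[elements]
  r[is.na(r)] <- model$radii[["C"]]
  unname(r) * model$scale
}

# analytic volume of the intersection of two spheres (lens), vectorized
lensVolume <- function(d, R1, R2) {
  v <- numeric(length(d))
  sep <- d >= R1 + R2
  inside <- !sep & d <= abs(R1 - R2)
  lens <- !sep & !inside
  v[inside] <- (4 / 3) * pi * pmin(R1, R2)[inside]^3
  dl <- d[lens]
  v[lens] <- pi * (R1[lens] + R2[lens] - dl)^2 *
    (dl^2 + 2 * dl * (R1[lens] + R2[lens]) - 3 * (R1[lens] - R2[lens])^2) /
    (12 * dl)
  v
}

#' Rigid-sphere overlap parameter between two atom sets
#'
#' A geometric proxy for the electronic-density overlap that controls the
#' short-range part of carotenoid-chlorophyll couplings: atoms are replaced
#' by rigid spheres and the parameter is the sum of all pairwise
#' sphere-intersection (lens) volumes between the two sets,
#' \deqn{O = \sum_{i \in A} \sum_{j \in B} v(r_{ij}; R_i, R_j)}
#' in cubic Angstrom. The lens volume is the exact analytic intersection
#' volume, zero at separations beyond R_i + R_j and equal to the smaller
#' sphere's volume at full containment. O is non-negative and non-increasing
#' as the sets are translated apart.
#'
#' @param coordsA,coordsB numeric matrices n x 3 (Angstrom).
#' @param radiiA,radiiB per-atom sphere radii (Angstrom); alternatively give
#'   \code{elementsA}/\code{elementsB} plus a \code{model}.
#' @param elementsA,elementsB element symbols used to look radii up.
#' @param model a \code{\link{sphereModel}} (default Bondi, scale 1).
#' @return the overlap parameter in Angstrom^3.
#' @export
overlapParameter <- function(coordsA, coordsB, radiiA = NULL, radiiB = NULL,
                             elementsA = NULL, elementsB = NULL,
                             model = sphereModel()) {
  if (is.null(radiiA)) radiiA <- sphereRadiiFor(elementsA, model)
  if (is.null(radiiB)) radiiB <- sphereRadiiFor(elementsB, model)
  if (any(radiiA <= 0) || any(radiiB <= 0)) stop("radii must be positive")
  D <- interatomicDistances(coordsA, coordsB)
  R1 <- matrix(radiiA, nrow(coordsA), nrow(coordsB))
  R2 <- matrix(radiiB, nrow(coordsA), nrow(coordsB), byrow = TRUE)
  sum(lensVolume(as.numeric(D), as.numeric(R1), as.numeric(R2)))
}

#' Per-frame couplings and overlaps for pigment pairs over an ensemble
#'
#' For every requested pigment pair and every frame: the transition-charge
#' Coulomb coupling V (cm^-1) and the rigid-sphere overlap parameter O
#' (Angstrom^3). Charges are matched onto the resolved selections by atom
#' name, in the order of the charge table; the overlap is computed on heavy
#' atoms only by default (hydrogens carry negligible density). The result
#' joins naturally with cluster labels for per-state distributions.
#'
#' @param ensemble a ConformationalEnsemble.
#' @param pairSpecs list of pair specifications, each a list with elements
#'   \code{id} (character), \code{selectionA}, \code{selectionB}
#'   (AtomSelection), \code{chargesA}, \code{chargesB}
#'   (\linkS4class{PigmentChargeSet}).
#' @param model a \code{\link{sphereModel}}.
#' @param includeHydrogens include H atoms in the overlap sum (default
#'   FALSE).
#' @return data.frame with columns frame, pair, vCoulomb, overlap.
#' @export
pairCouplingsOverEnsemble <- function(ensemble, pairSpecs,
                                      model = sphereModel(),
                                      includeHydrogens = FALSE) {
  top <- topology(ensemble)
  prep <- lapply(pairSpecs, function(ps) {
    ixA <- resolveSelection(ensemble, ps$selectionA)
    ixB <- resolveSelection(ensemble, ps$selectionB)
    mapCharges <- function(ix, cs) {
      pos <- match(cs@atomNames, top$elety[ix])
      if (anyNA(pos))
        stop("pair ", ps$id, ": charge-table atom(s) not found: ",
             paste(cs@atomNames[is.na(pos)], collapse = ", "))
      ix[pos]
    }
    qA <- mapCharges(ixA, ps$chargesA)
    qB <- mapCharges(ixB, ps$chargesB)
    heavyA <- ixA[includeHydrogens | top$elesy[ixA] != "H"]
    heavyB <- ixB[includeHydrogens | top$elesy[ixB] != "H"]
    list(id = ps$id, qAidx = qA, qBidx = qB,
         qA = ps$chargesA@charges, qB = ps$chargesB@charges,
         heavyA = heavyA, heavyB = heavyB,
         radA = sphereRadiiFor(top$elesy[heavyA], model),
         radB = sphereRadiiFor(top$elesy[heavyB], model))
  })
  nfr <- nFrames(ensemble)
  rows <- vector("list", nfr * length(prep))
  k <- 0L
  for (f in seq_len(nfr)) {
    xyz <- frameCoords(ensemble, f)
    for (p in prep) {
      v <- coulombCoupling(xyz[p$qAidx, , drop = FALSE], p$qA,
                           xyz[p$qBidx, , drop = FALSE], p$qB)
      o <- overlapParameter(xyz[p$heavyA, , drop = FALSE],
                            xyz[p$heavyB, , drop = FALSE],
                            radiiA = p$radA, radiiB = p$radB)
      k <- k + 1L
      rows[[k]] <- data.frame(frame = f, pair = p$id,
                              vCoulomb = v, overlap = o,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
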