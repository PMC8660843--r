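#' Define the four nodes of an inter-helical torsion
#'
#' The P1 collective variable is the torsion of four "nodes" A2-A1-B1-B2,
#' each node being the centre of geometry of a group of atoms on helix A or
#' helix B (typically the CA atoms of a few consecutive residues on the
#' lumenal or stromal half of each helix). Splitting P1 into a lumenal
#' (P1_l) and a stromal (P1_s) variant captures the two sides of the
#' complex separately.
#'
#' @param A2,A1,B1,B2 \linkS4class{AtomSelection}s; their resolved atom sets
#'   must be non-empty and mutually disjoint.
#' @param variant "lumenal" or "stromal" (a label carried into outputs).
#' @return a list of class "HelixNodeSpec".
#' @export
helixNodeSpec <- function(A2, A1, B1, B2, variant = c("lumenal", "stromal")) {
  variant <- match.arg(variant)
  structure(list(A2 = A2, A1 = A1, B1 = B1, B2 = B2, variant = variant),
            class = "HelixNodeSpec")
}

#' Inter-helical torsion P1 per frame
#'
#' Torsion of the four node centres of geometry, same sign convention as
#' \code{\link{torsionAngle}}, reported in degrees in (-180, 180]. Being a
#' function of internal geometry only, it is invariant under rigid-body
#' motion of the frame. Frames with collinear nodes are flagged NA.
#'
#' @param ensemble a ConformationalEnsemble.
#' @param nodeSpec a \code{\link{helixNodeSpec}}.
#' @return numeric vector, one torsion (degrees) per frame.
#' @export
computeP1 <- function(ensemble, nodeSpec) {
  sel <- lapply(nodeSpec[c("A2", "A1", "B1", "B2")],
                function(s) resolveSelection(ensemble, s))
  for (i in 1:3) for (j in (i + 1):4)
    if (length(intersect(sel[[i]], sel[[j]])))
      stop("node selections must be mutually disjoint (",
           names(sel)[i], " overlaps ", names(sel)[j], ")")
  nfr <- nFrames(ensemble)
  out <- numeric(nfr)
  for (f in seq_len(nfr)) {
    xyz <- frameCoords(ensemble, f)
    ctr <- vapply(sel, function(ix) colMeans(xyz[ix, , drop = FALSE]),
                  numeric(3))
    out[f] <- torsionAngle(ctr[, 1], ctr[, 2], ctr[, 3], ctr[, 4]) * 180 / pi
  }
  out
}

#' Conjugated-chain dihedrals of a carotenoid
#'
#' All consecutive four-atom torsions along an ordered atom list (the
#' conjugated chain), named d1..dN counting from the declared lumenal end.
#' Values in degrees, (-180, 180]; each dihedral is also classified as
#' s-cis or s-trans.
#'
#' @param ensemble a ConformationalEnsemble.
#' @param atomNames ordered atom names of the chain (>= 4), starting at the
#'   lumenal end.
#' @param selection optional AtomSelection narrowing the atom-name lookup
#'   (e.g. the carotenoid's chain/residue).
#' @return list with \code{angles} (frames x dihedrals matrix, degrees,
#'   columns d1..dN) and \code{conformer} (same shape, "s-cis"/"s-trans").
#' @export
computeCarDihedrals <- function(ensemble, atomNames, selection = NULL) {
  if (length(atomNames) < 4L) stop("need at least 4 ordered atoms")
  top <- topology(ensemble)
  pool <- if (is.null(selection)) seq_len(nrow(top))
          else resolveSelection(ensemble, selection)
  idx <- vapply(atomNames, function(nm) {
    hit <- pool[top$elety[pool] == nm]
    if (!length(hit)) stop("atom not found in selection: ", nm)
    hit[1]
  }, integer(1))
  nd <- length(idx) - 3L
  nfr <- nFrames(ensemble)
  ang <- matrix(NA_real_, nfr, nd,
                dimnames = list(NULL, paste0("d", seq_len(nd))))
  for (f in seq_len(nfr)) {
    xyz <- frameCoords(ensemble, f)
    ang[f, ] <- torsionAngle(xyz[idx[1:nd], , drop = FALSE],
                             xyz[idx[2:(nd + 1)], , drop = FALSE],
                             xyz[idx[3:(nd + 2)], , drop = FALSE],
                             xyz[idx[4:(nd + 3)], , drop = FALSE]) * 180 / pi
  }
  conf <- matrix(classifyConformer(ang), nrow(ang), ncol(ang),
                 dimnames = dimnames(ang))
  list(angles = ang, conformer = conf)
}

#' Classify a conjugated-bond dihedral as s-cis or s-trans
#'
#' A single-bond conformer near 0 degrees is s-cis, near 180 degrees
#' s-trans; the boundary is at |angle| = 90 degrees and is assigned to
#' s-trans. The two conformers interconvert by the pedaling motion of the
#' chain.
#'
#' @param angleDeg dihedral(s) in degrees (finite; NA propagates).
#' @return character vector "s-cis"/"s-trans".
#' @export
classifyConformer <- function(angleDeg) {
  out <- ifelse(abs(wrapAngle(angleDeg * pi / 180)) * 180 / pi < 90,
                "s-cis", "s-trans")
  out[!is.finite(angleDeg)] <- NA_character_
  out
}

#' Box-plot statistics per group
#'
#' Median, first and third quartile (linear interpolation, quantile type 7),
#' whiskers extending to the most extreme data point within 1.5 IQR of the
#' box, and the outliers beyond the whiskers — the statistics drawn in the
#' per-cluster box plots of carotenoid dihedrals and S1 energies. With
#' \code{circular = TRUE} (for angular data in degrees) values are first
#' recentred about their circular mean so that a distribution straddling the
#' +-180 branch cut is summarised without wrap bias; recentring is applied
#' only when the linear spread exceeds 90 degrees.
#'
#' @param values numeric vector.
#' @param groups optional grouping (e.g. cluster labels); NULL = one group.
#' @param circular treat values as angles in degrees.
#' @return data.frame with one row per group: group, n, median, q1, q3,
#'   whiskerLow, whiskerHigh, nOutliers; the outlier values are attached as
#'   the "outliers" attribute (a list).
#' @export
distributionSummary <- function(values, groups = NULL, circular = FALSE) {
  if (is.null(groups)) groups <- rep(0L, length(values))
  if (!length(values)) stop("no values")
  levs <- sort(unique(groups))
  rows <- vector("list", length(levs))
  outl <- vector("list", length(levs))
  for (i in seq_along(levs)) {
    v <- values[groups == levs[i]]
    v <- v[is.finite(v)]
    if (!length(v)) stop("empty group: ", levs[i])
    if (circular && diff(range(v)) > 90) {
      mu <- atan2(mean(sin(v * pi / 180)), mean(cos(v * pi / 180))) * 180 / pi
      v <- mu + wrapAngle((v - mu) * pi / 180) * 180 / pi
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr])
    hi <- max(v[v <= q[3] + 1.5 * iqr])
    out <- v[v < lo | v > hi]
    rows[[i]] <- data.frame(group = levs[i], n = length(v),
                            median = q[2], q1 = q[1], q3 = q[3],
                            whiskerLow = lo, whiskerHigh = hi,
                            nOutliers = length(out))
    outl[[i]] <- out
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "outliers") <- outl
  res
}
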