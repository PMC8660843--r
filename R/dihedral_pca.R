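#' Build the default protein dihedral specification
#'
#' Enumerates backbone phi and psi for every residue that has the required
#' neighbours, plus sidechain chi1 (N-CA-CB-CG) where CB and CG exist.
#' Dihedrals are defined on atom indices, so the spec can be audited and
#' filtered before computing angles.
#'
#' @param ensemble a ConformationalEnsemble.
#' @param chi1 include chi1 angles (default TRUE).
#' @param resno optional residue-number filter.
#' @return data.frame with columns resno, dihedral, i, j, k, l (atom indices).
#' @export
proteinDihedralSpec <- function(ensemble, chi1 = TRUE, resno = NULL) {
  top <- topology(ensemble)
  key <- paste(top$chain, top$resno, sep = "|")
  resKeys <- unique(key)
  atomOf <- function(k, name) {
    ix <- which(key == k & top$elety == name)
    if (length(ix)) ix[1] else NA_integer_
  }
  rows <- list()
  for (r in seq_along(resKeys)) {
    k <- resKeys[r]
    rn <- top$resno[match(k, key)]
    if (!is.null(resno) && !(rn %in% resno)) next
    N <- atomOf(k, "N"); CA <- atomOf(k, "CA"); C <- atomOf(k, "C")
    prevC <- if (r > 1) atomOf(resKeys[r - 1], "C") else NA_integer_
    nextN <- if (r < length(resKeys)) atomOf(resKeys[r + 1], "N") else NA_integer_
    if (!anyNA(c(prevC, N, CA, C)))
      rows[[length(rows) + 1L]] <- data.frame(
        resno = rn, dihedral = "phi", i = prevC, j = N, k = CA, l = C)
    if (!anyNA(c(N, CA, C, nextN)))
      rows[[length(rows) + 1L]] <- data.frame(
        resno = rn, dihedral = "psi", i = N, j = CA, k = C, l = nextN)
    if (chi1) {
      CB <- atomOf(k, "CB"); CG <- atomOf(k, "CG")
      if (!anyNA(c(N, CA, CB, CG)))
        rows[[length(rows) + 1L]] <- data.frame(
          resno = rn, dihedral = "chi1", i = N, j = CA, k = CB, l = CG)
    }
  }
  if (!length(rows)) stop("no dihedrals definable on this topology")
  do.call(rbind, rows)
}

#' Compute dihedral angles over all frames
#'
#' Torsion per frame per requested dihedral, IUPAC right-hand-rule sign,
#' range (-pi, pi]. Frames where a torsion is undefined (collinear central
#' atoms) carry NA for that feature.
#'
#' @param ensemble a ConformationalEnsemble.
#' @param spec data.frame as returned by \code{\link{proteinDihedralSpec}}
#'   (columns resno, dihedral, i, j, k, l).
#' @return a \linkS4class{DihedralFeatures}.
#' @export
computeDihedrals <- function(ensemble, spec) {
  nat <- nAtoms(ensemble)
  idx <- as.matrix(spec[, c("i", "j", "k", "l")])
  if (any(idx < 1 | idx > nat) || anyNA(idx))
    stop("dihedral spec references atoms outside the topology")
  nfr <- nFrames(ensemble)
  ang <- matrix(NA_real_, nfr, nrow(spec))
  for (f in seq_len(nfr)) {
    xyz <- frameCoords(ensemble, f)
    ang[f, ] <- torsionAngle(xyz[spec$i, , drop = FALSE],
                             xyz[spec$j, , drop = FALSE],
                             xyz[spec$k, , drop = FALSE],
                             xyz[spec$l, , drop = FALSE])
  }
  colnames(ang) <- paste0(spec$dihedral, spec$resno)
  new("DihedralFeatures", angles = ang,
      labels = data.frame(resno = spec$resno, dihedral = spec$dihedral,
                          stringsAsFactors = FALSE))
}

#' Circular (sin/cos) embedding of dihedral features
#'
#' Maps each angle theta to the pair (cos theta, sin theta); columns are
#' interleaved per feature (cos1, sin1, cos2, sin2, ...). This removes the
#' branch cut at +-pi before PCA, which is the essence of dihedral PCA.
#'
#' @param features a \linkS4class{DihedralFeatures}.
#' @return numeric matrix frames x (2 * nFeatures).
#' @export
circularEmbed <- function(features) {
  a <- features@angles
  p <- ncol(a)
  out <- matrix(NA_real_, nrow(a), 2 * p)
  out[, 2 * seq_len(p) - 1] <- cos(a)
  out[, 2 * seq_len(p)] <- sin(a)
  cn <- colnames(a)
  if (is.null(cn))
    cn <- paste0(features@labels$dihedral, features@labels$resno)
  colnames(out) <- as.vector(rbind(paste0("cos.", cn), paste0("sin.", cn)))
  out
}

#' Decode a circular embedding back to angles
#' @param embedded matrix as produced by \code{\link{circularEmbed}}.
#' @return matrix of angles, radians in (-pi, pi].
#' @export
circularDecode <- function(embedded) {
  p <- ncol(embedded) / 2
  atan2(embedded[, 2 * seq_len(p), drop = FALSE],
        embedded[, 2 * seq_len(p) - 1, drop = FALSE])
}

#' Fit a (weighted) PCA on embedded dihedral features
#'
#' Weighted-mean-centred principal component analysis: eigendecomposition
#' of the weighted covariance C = X_c' diag(w) X_c / sum(w). Eigenvalues are
#' sorted in decreasing order and clipped at zero; the sign of each
#' component is fixed so that its largest-magnitude loading is positive
#' (ties broken by the lowest feature index), making the model reproducible.
#'
#' @param embedded numeric matrix frames x features.
#' @param weights optional frame weights (default uniform).
#' @return a \linkS4class{DihedralPCA}.
#' @export
fitDihedralPCA <- function(embedded, weights = NULL) {
  n <- nrow(embedded)
  if (n < 2L) stop("PCA needs at least two frames")
  if (is.null(weights)) weights <- rep(1, n)
  W <- sum(weights)
  if (W <= 0) stop("total frame weight must be positive")
  w <- weights / W
  mu <- colSums(embedded * w)
  Xc <- sweep(embedded, 2, mu)
  C <- crossprod(Xc * w, Xc)
  C <- (C + t(C)) / 2
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  comp <- t(eg$vectors)
  for (i in seq_len(nrow(comp))) {
    jmax <- which.max(abs(comp[i, ]))
    if (comp[i, jmax] < 0) comp[i, ] <- -comp[i, ]
  }
  new("DihedralPCA", center = mu, components = comp,
      eigenvalues = ev, nFeatures = ncol(embedded))
}

setMethod("show", "DihedralPCA", function(object) {
  ev <- object@eigenvalues
  tot <- sum(ev)
  k <- min(3L, length(ev))
  frac <- if (tot > 0) ev[seq_len(k)] / tot else rep(0, k)
  cat("DihedralPCA on", object@nFeatures, "embedded features\n")
  cat("  explained variance PC1..PC", k, ": ",
      paste(sprintf("%.1f%%", 100 * frac), collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

#' Project embedded features onto principal components
#'
#' Scores are the centred data times the component vectors. With uniform
#' weights the weighted variance of score column k equals eigenvalue k.
#'
#' @param model a \linkS4class{DihedralPCA}.
#' @param embedded matrix with the same feature count the model was fit on.
#' @param nComponents number of leading components to keep (default 3).
#' @return numeric score matrix frames x nComponents.
#' @export
projectFrames <- function(model, embedded, nComponents = 3L) {
  if (is.null(dim(embedded))) embedded <- matrix(embedded, 1)
  if (ncol(embedded) != model@nFeatures)
    stop("feature count (", ncol(embedded), ") does not match the model (",
         model@nFeatures, ")")
  nComponents <- min(nComponents, nrow(model@components))
  Xc <- sweep(embedded, 2, model@center)
  sc <- Xc %*% t(model@components[seq_len(nComponents), , drop = FALSE])
  colnames(sc) <- paste0("PC", seq_len(nComponents))
  sc
}

#' Free-energy surface from a 2D projection
#'
#' Boltzmann inversion of the (weighted) bin occupancy:
#' F(bin) = -kT log(w(bin) / w(max bin)), so the most occupied bin sits at
#' F = 0 and empty bins are Inf (undefined). Scaling all weights by a
#' constant leaves F unchanged.
#'
#' @param x,y coordinates per frame (e.g. two score columns or two CVs).
#' @param weights frame weights (default uniform).
#' @param bins number of bins per axis (scalar or length-2).
#' @param kT energy unit (default 1, i.e. F in units of kT).
#' @param xlim,ylim optional axis ranges; default data range.
#' @return a \linkS4class{FreeEnergySurface}.
#' @export
freeEnergySurface <- function(x, y, weights = NULL, bins = 40, kT = 1,
                              xlim = NULL, ylim = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  if (all(weights == 0)) stop("all frame weights are zero")
  bins <- rep(bins, length.out = 2)
  if (is.null(xlim)) xlim <- range(x)
  if (is.null(ylim)) ylim <- range(y)
  xe <- seq(xlim[1], xlim[2], length.out = bins[1] + 1)
  ye <- seq(ylim[1], ylim[2], length.out = bins[2] + 1)
  ix <- findInterval(x, xe, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, ye, rightmost.closed = TRUE, all.inside = TRUE)
  W <- matrix(0, bins[1], bins[2])
  for (i in seq_along(x)) W[ix[i], iy[i]] <- W[ix[i], iy[i]] + weights[i]
  Fm <- matrix(Inf, bins[1], bins[2])
  occ <- W > 0
  Fm[occ] <- -kT * log(W[occ] / max(W))
  new("FreeEnergySurface", xEdges = xe, yEdges = ye, surface = Fm, kT = kT)
}

setMethod("show", "FreeEnergySurface", function(object) {
  fin <- object@surface[is.finite(object@surface)]
  cat("FreeEnergySurface:", nrow(object@surface), "x", ncol(object@surface),
      "bins,", length(fin), "occupied, max F =",
      sprintf("%.2f", max(fin)), "kT\n")
  invisible(NULL)
})

#' Per-residue root-mean-square fluctuations
#'
#' Frames are superposed onto the ensemble mean structure by weighted Kabsch
#' alignment (the mean is refined iteratively; two passes). The RMSF of a
#' residue is the square root of the weighted mean squared deviation of its
#' atoms from the mean structure, in Angstrom.
#'
#' @param ensemble a ConformationalEnsemble with >= 2 frames.
#' @param selection optional AtomSelection restricting the atoms used both
#'   for alignment and for reporting (default: all atoms).
#' @param iterations mean-refinement passes (default 2).
#' @return data.frame with columns chain, resno, rmsf.
#' @export
residueFluctuations <- function(ensemble, selection = NULL, iterations = 2L) {
  nfr <- nFrames(ensemble)
  if (nfr < 2L) stop("RMSF needs at least two frames")
  idx <- if (is.null(selection)) seq_len(nAtoms(ensemble))
         else resolveSelection(ensemble, selection)
  w <- frameWeights(ensemble)
  w <- w / sum(w)
  X <- lapply(seq_len(nfr), function(f) frameCoords(ensemble, f)[idx, , drop = FALSE])
  ref <- X[[1]]
  for (it in seq_len(iterations)) {
    Xal <- lapply(X, kabschAlign, Q = ref)
    ref <- Reduce(`+`, Map(function(m, wi) m * wi, Xal, w))
  }
  Xal <- lapply(X, kabschAlign, Q = ref)
  msd <- Reduce(`+`, Map(function(m, wi) wi * rowSums((m - ref)^2), Xal, w))
  top <- topology(ensemble)[idx, , drop = FALSE]
  key <- paste(top$chain, top$resno, sep = "|")
  agg <- tapply(msd, key, mean)
  ord <- unique(key)
  data.frame(
    chain = top$chain[match(ord, key)],
    resno = top$resno[match(ord, key)],
    rmsf = sqrt(as.numeric(agg[ord])),
    stringsAsFactors = FALSE
  )
}
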