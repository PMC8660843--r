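#' @import methods
NULL

#' ConformationalEnsemble: frames x atoms x 3 coordinates with a topology
#'
#' The central container of the package: a conformational ensemble of a
#' pigment-protein complex (for example the frames of an enhanced-sampling
#' trajectory, read from a multi-model PDB). Coordinates are in Angstrom.
#' The topology is a data.frame with one row per atom and columns
#' \code{chain}, \code{resid} (residue name), \code{resno} (residue number,
#' as in the file), \code{elety} (atom name) and \code{elesy} (element
#' symbol). \code{frameWeights} are non-negative per-frame weights
#' (uniform by default); they enter weighted means, dPCA and free-energy
#' surfaces.
#'
#' @slot coords numeric array \code{[nFrames, nAtoms, 3]}, Angstrom.
#' @slot topology data.frame, one row per atom (shared by all frames).
#' @slot frameWeights numeric vector of length \code{nFrames}.
#' @slot metadata list of free-form provenance (seed, generator spec, ...).
#' @exportClass ConformationalEnsemble
setClass("ConformationalEnsemble",
  representation(
    coords = "array",
    topology = "data.frame",
    frameWeights = "numeric",
    metadata = "list"
  )
)

setValidity("ConformationalEnsemble", function(object) {
  d <- dim(object@coords)
  msg <- character(0)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be a [frames, atoms, 3] array")
  else {
    if (d[1] < 1L) msg <- c(msg, "ensemble needs at least one frame")
    if (nrow(object@topology) != d[2])
      msg <- c(msg, "topology rows must match the atom dimension of coords")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    if (length(object@frameWeights) != d[1])
      msg <- c(msg, "frameWeights length must equal the number of frames")
    if (any(object@frameWeights < 0) || sum(object@frameWeights) <= 0)
      msg <- c(msg, "frameWeights must be non-negative with positive sum")
  }
  need <- c("chain", "resid", "resno", "elety", "elesy")
  if (!all(need %in% names(object@topology)))
    msg <- c(msg, paste("topology must have columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PigmentChargeSet: transition charges of one pigment
#'
#' An ordered atom list carrying the atomic point charges (TrESP-style) that
#' represent one electronic transition density of a pigment, e.g. the
#' carotenoid S1->S0 or the chlorophyll Qy transition. Charges are in units
#' of the elementary charge e. Coordinates are optional (0-row matrix when
#' the set is purely a charge template to be matched onto an ensemble).
#'
#' @slot pigmentId character scalar, e.g. "LUT" or "CLA612".
#' @slot transition character scalar label, e.g. "S1-Qy".
#' @slot atomNames character vector, order defines the charge order.
#' @slot charges numeric vector (e), same length as atomNames.
#' @slot coords numeric matrix n x 3 (Angstrom) or 0 x 3 when absent.
#' @exportClass PigmentChargeSet
setClass("PigmentChargeSet",
  representation(
    pigmentId = "character",
    transition = "character",
    atomNames = "character",
    charges = "numeric",
    coords = "matrix"
  )
)

setValidity("PigmentChargeSet", function(object) {
  msg <- character(0)
  if (length(object@atomNames) != length(object@charges))
    msg <- c(msg, "atomNames and charges must have equal length")
  if (anyDuplicated(object@atomNames))
    msg <- c(msg, "duplicate atom names in charge set")
  if (!all(is.finite(object@charges)))
    msg <- c(msg, "charges must be finite")
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "coords must have 3 columns")
  if (nrow(object@coords) != 0L &&
      nrow(object@coords) != length(object@atomNames))
    msg <- c(msg, "coords rows must match atomNames (or be empty)")
  if (length(msg)) msg else TRUE
})

#' DihedralFeatures: frames x dihedral-angle matrix with feature labels
#'
#' @slot angles numeric matrix frames x features, radians in (-pi, pi];
#'   NA marks a torsion undefined in that frame (collinear central atoms).
#' @slot labels data.frame with columns \code{resno} and \code{dihedral}
#'   (one of "phi", "psi", "chi1" or a custom name), one row per column of
#'   \code{angles}.
#' @exportClass DihedralFeatures
setClass("DihedralFeatures",
  representation(angles = "matrix", labels = "data.frame")
)

setValidity("DihedralFeatures", function(object) {
  msg <- character(0)
  if (nrow(object@labels) != ncol(object@angles))
    msg <- c(msg, "labels must have one row per angle column")
  if (!all(c("resno", "dihedral") %in% names(object@labels)))
    msg <- c(msg, "labels needs columns resno and dihedral")
  a <- object@angles[is.finite(object@angles)]
  if (length(a) && (any(a <= -pi - 1e-9) || any(a > pi + 1e-9)))
    msg <- c(msg, "angles must lie in (-pi, pi]")
  if (length(msg)) msg else TRUE
})

#' DihedralPCA: a fitted (weighted) PCA on circularly embedded dihedrals
#'
#' @slot center numeric, weighted mean of the embedded features.
#' @slot components numeric matrix, one orthonormal component per row.
#' @slot eigenvalues numeric, non-increasing, >= 0; eigenvalue k is the
#'   weighted variance of the data along component k.
#' @slot nFeatures integer, embedded-feature count the model was fit on.
#' @exportClass DihedralPCA
setClass("DihedralPCA",
  representation(
    center = "numeric",
    components = "matrix",
    eigenvalues = "numeric",
    nFeatures = "integer"
  )
)

setValidity("DihedralPCA", function(object) {
  msg <- character(0)
  if (ncol(object@components) != object@nFeatures)
    msg <- c(msg, "component columns must equal nFeatures")
  if (length(object@center) != object@nFeatures)
    msg <- c(msg, "center length must equal nFeatures")
  if (length(object@eigenvalues) != nrow(object@components))
    msg <- c(msg, "one eigenvalue per component required")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (any(object@eigenvalues < -1e-8))
    msg <- c(msg, "eigenvalues must be non-negative")
  G <- tcrossprod(object@components)
  if (max(abs(G - diag(nrow(G)))) > 1e-8)
    msg <- c(msg, "components must be mutually orthonormal")
  if (length(msg)) msg else TRUE
})

#' ClusterModel: conformational-state assignment of ensemble frames
#'
#' @slot labels integer vector, 0-based cluster id per frame; clusters are
#'   relabeled by descending size (cluster 0 is the largest).
#' @slot linkage character, the agglomeration method.
#' @slot metric character, the distance metric.
#' @slot nClusters integer.
#' @slot counts integer vector of per-cluster frame counts.
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(
    labels = "integer",
    linkage = "character",
    metric = "character",
    nClusters = "integer",
    counts = "integer"
  )
)

setValidity("ClusterModel", function(object) {
  msg <- character(0)
  k <- object@nClusters
  if (!identical(sort(unique(object@labels)), seq_len(k) - 1L))
    msg <- c(msg, "labels must be contiguous 0-based cluster ids")
  if (length(object@counts) != k || sum(object@counts) != length(object@labels))
    msg <- c(msg, "counts must sum to the number of frames")
  if (length(msg)) msg else TRUE
})

#' FreeEnergySurface: -kT log density on a 2D grid, shifted so min = 0
#'
#' Empty bins carry \code{Inf} (free energy undefined where nothing was
#' sampled); values are in units of kT unless another temperature factor was
#' supplied.
#'
#' @slot xEdges,yEdges numeric bin edges.
#' @slot surface numeric matrix \code{(length(xEdges)-1) x (length(yEdges)-1)}.
#' @slot kT numeric, the energy unit used.
#' @exportClass FreeEnergySurface
setClass("FreeEnergySurface",
  representation(
    xEdges = "numeric", yEdges = "numeric",
    surface = "matrix", kT = "numeric"
  )
)

setValidity("FreeEnergySurface", function(object) {
  msg <- character(0)
  if (!identical(dim(object@surface),
                 c(length(object@xEdges) - 1L, length(object@yEdges) - 1L)))
    msg <- c(msg, "surface dimensions must match the bin edges")
  fin <- object@surface[is.finite(object@surface)]
  if (length(fin)) {
    if (min(fin) < -1e-9) msg <- c(msg, "free energies must be >= 0")
    if (abs(min(fin)) > 1e-9) msg <- c(msg, "minimum free energy must be 0")
  }
  if (length(msg)) msg else TRUE
})

#' AtomSelection: a predicate over topology fields
#'
#' Any field left NULL matches everything; \code{resno} may be a range or an
#' explicit vector of residue numbers.
#'
#' @slot chain character or NULL.
#' @slot resno integer vector or NULL.
#' @slot resid character vector (residue names) or NULL.
#' @slot elety character vector (atom names) or NULL.
#' @exportClass AtomSelection
setClass("AtomSelection",
  representation(chain = "ANY", resno = "ANY", resid = "ANY", elety = "ANY")
)
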