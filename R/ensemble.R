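#' Construct a ConformationalEnsemble
#'
#' @param coords numeric array [frames, atoms, 3] (Angstrom).
#' @param topology data.frame with columns chain, resid, resno, elety, elesy.
#' @param frameWeights optional per-frame weights; default uniform.
#' @param metadata optional list of provenance.
#' @return A \linkS4class{ConformationalEnsemble}.
#' @export
ConformationalEnsemble <- function(coords, topology, frameWeights = NULL,
                                   metadata = list()) {
  if (is.null(frameWeights)) frameWeights <- rep(1, dim(coords)[1])
  topology$chain <- as.character(topology$chain)
  topology$resid <- as.character(topology$resid)
  topology$resno <- as.integer(topology$resno)
  topology$elety <- as.character(topology$elety)
  topology$elesy <- as.character(topology$elesy)
  rownames(topology) <- NULL
  new("ConformationalEnsemble", coords = coords, topology = topology,
      frameWeights = as.numeric(frameWeights), metadata = metadata)
}

#' @rdname ConformationalEnsemble
#' @param object,x a ConformationalEnsemble
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname ConformationalEnsemble
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname ConformationalEnsemble
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname ConformationalEnsemble
#' @export
setGeneric("frameWeights", function(x) standardGeneric("frameWeights"))
#' @rdname ConformationalEnsemble
#' @export
setGeneric("ensembleMetadata", function(x) standardGeneric("ensembleMetadata"))
#' Coordinates of one frame or the whole ensemble
#' @param x a ConformationalEnsemble
#' @param frame frame index; NULL returns the full array
#' @export
setGeneric("frameCoords", function(x, frame = NULL) standardGeneric("frameCoords"))

#' @rdname ConformationalEnsemble
setMethod("nFrames", "ConformationalEnsemble", function(x) dim(x@coords)[1])
#' @rdname ConformationalEnsemble
setMethod("nAtoms", "ConformationalEnsemble", function(x) dim(x@coords)[2])
#' @rdname ConformationalEnsemble
setMethod("topology", "ConformationalEnsemble", function(x) x@topology)
#' @rdname ConformationalEnsemble
setMethod("frameWeights", "ConformationalEnsemble", function(x) x@frameWeights)
#' @rdname ConformationalEnsemble
setMethod("ensembleMetadata", "ConformationalEnsemble", function(x) x@metadata)

#' @rdname frameCoords
setMethod("frameCoords", "ConformationalEnsemble", function(x, frame = NULL) {
  if (is.null(frame)) return(x@coords)
  m <- x@coords[frame, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
})

setMethod("show", "ConformationalEnsemble", function(object) {
  top <- object@topology
  cat("ConformationalEnsemble:", dim(object@coords)[1], "frames,",
      dim(object@coords)[2], "atoms,",
      length(unique(paste(top$chain, top$resno))), "residues\n")
  cat("  chains:", paste(unique(top$chain), collapse = ", "), "\n")
  w <- object@frameWeights
  if (length(unique(w)) > 1L)
    cat("  frame weights: non-uniform (sum", format(sum(w)), ")\n")
  invisible(NULL)
})

#' Subset an ensemble to selected frames
#' @param x a ConformationalEnsemble
#' @param frames integer frame indices
#' @return a ConformationalEnsemble with those frames
#' @export
subsetFrames <- function(x, frames) {
  ConformationalEnsemble(x@coords[frames, , , drop = FALSE], x@topology,
                         x@frameWeights[frames], x@metadata)
}

#' Define an atom selection
#'
#' A predicate over the topology fields; \code{NULL} fields match all atoms.
#'
#' @param chain chain identifier(s).
#' @param resno residue numbers (vector or range, e.g. \code{10:25}).
#' @param resid residue name(s).
#' @param elety atom name(s), e.g. \code{"CA"}.
#' @return an \linkS4class{AtomSelection}.
#' @export
atomSelection <- function(chain = NULL, resno = NULL, resid = NULL,
                          elety = NULL) {
  new("AtomSelection", chain = chain,
      resno = if (is.null(resno)) NULL else as.integer(resno),
      resid = resid, elety = elety)
}

#' Resolve an atom selection against an ensemble topology
#'
#' Deterministic: returns indices in topology order. Resolution is a pure
#' function of (topology, predicate).
#'
#' @param ensemble a ConformationalEnsemble.
#' @param selection an AtomSelection.
#' @return integer vector of atom indices (1-based, topology order).
#' @export
resolveSelection <- function(ensemble, selection) {
  top <- topology(ensemble)
  keep <- rep(TRUE, nrow(top))
  if (!is.null(selection@chain)) keep <- keep & top$chain %in% selection@chain
  if (!is.null(selection@resno)) keep <- keep & top$resno %in% selection@resno
  if (!is.null(selection@resid)) keep <- keep & top$resid %in% selection@resid
  if (!is.null(selection@elety)) keep <- keep & top$elety %in% selection@elety
  idx <- which(keep)
  if (!length(idx)) {
    desc <- c(
      if (!is.null(selection@chain))
        paste0("chain=", paste(selection@chain, collapse = ",")),
      if (!is.null(selection@resno))
        paste0("resno=", paste(range(selection@resno), collapse = "-")),
      if (!is.null(selection@resid))
        paste0("resid=", paste(selection@resid, collapse = ",")),
      if (!is.null(selection@elety))
        paste0("elety=", paste(selection@elety, collapse = ",")))
    stop("selection resolves to no atoms (",
         paste(desc, collapse = " "), ")")
  }
  idx
}
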