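#' Read a multi-model PDB file into a ConformationalEnsemble
#'
#' One frame per MODEL record; a single-model file yields a one-frame
#' ensemble. The topology is taken from the first model; all models must
#' share the atom count (enforced by the underlying parser). Residue
#' numbering is kept exactly as in the file.
#'
#' @param path path to a PDB file.
#' @return a \linkS4class{ConformationalEnsemble}.
#' @export
readMultimodelPDB <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nat <- nrow(pdb$atom)
  nfr <- nrow(xyz)
  coords <- array(NA_real_, c(nfr, nat, 3))
  for (f in seq_len(nfr)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  elesy <- pdb$atom$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nat)
  miss <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[miss] <- guessElement(pdb$atom$elety[miss])
  top <- data.frame(
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    resid = pdb$atom$resid,
    resno = pdb$atom$resno,
    elety = pdb$atom$elety,
    elesy = trimws(elesy),
    stringsAsFactors = FALSE
  )
  ConformationalEnsemble(coords, top, metadata = list(source = path))
}

#' Write a ConformationalEnsemble as a multi-model PDB
#'
#' MODEL/ENDMDL records, one per frame; coordinates at PDB precision
#' (3 decimals).
#'
#' @param ensemble a ConformationalEnsemble.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMultimodelPDB <- function(ensemble, path) {
  top <- topology(ensemble)
  nfr <- nFrames(ensemble)
  nat <- nAtoms(ensemble)
  xyz <- matrix(NA_real_, nfr, 3 * nat)
  for (f in seq_len(nfr)) {
    xyz[f, ] <- as.numeric(t(frameCoords(ensemble, f)))
  }
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = top$resno, resid = top$resid,
                   chain = top$chain, elety = top$elety,
                   eleno = seq_len(nat), elesy = top$elesy)
  invisible(path)
}

# element symbol from a PDB atom name: strip digits/primes, keep a known
# two-letter symbol if it matches, else the first letter
guessElement <- function(elety) {
  two <- c("MG", "CL", "BR", "FE", "ZN", "MN", "NA", "CA_ION")
  vapply(elety, function(a) {
    s <- gsub("[0-9'\"]", "", trimws(a))
    if (toupper(s) %in% two) {
      su <- toupper(s)
      paste0(substr(su, 1, 1), tolower(substr(su, 2, 2)))
    } else {
      substr(s, 1, 1)
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Read a transition-charge table
#'
#' Tab-separated with a mandatory header and '#' comment lines; columns
#' \code{atom_name} and \code{charge_e} (elementary-charge units). Row
#' order defines the charge order; duplicate atom names are rejected.
#'
#' @param path path to the TSV file.
#' @param pigmentId identifier stored in the result (default: file stem).
#' @param transition transition label, e.g. "S1-Qy".
#' @return a \linkS4class{PigmentChargeSet} (without coordinates).
#' @export
readChargeTable <- function(path, pigmentId = NULL, transition = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("atom_name", "charge_e") %in% names(tab)))
    stop("charge table needs columns atom_name and charge_e: ", path)
  if (nrow(tab) == 0L) stop("charge table has no data rows: ", path)
  q <- suppressWarnings(as.numeric(tab$charge_e))
  if (anyNA(q)) stop("non-numeric charge in ", path, " at row ",
                     which(is.na(q))[1])
  if (anyDuplicated(tab$atom_name))
    stop("duplicate atom name in ", path, ": ",
         tab$atom_name[anyDuplicated(tab$atom_name)])
  if (is.null(pigmentId))
    pigmentId <- sub("\\.[^.]*$", "", basename(path))
  new("PigmentChargeSet", pigmentId = pigmentId, transition = transition,
      atomNames = tab$atom_name, charges = q,
      coords = matrix(numeric(0), 0, 3))
}

#' Write a PigmentChargeSet as a charge table
#' @param chargeSet a PigmentChargeSet.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeChargeTable <- function(chargeSet, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pigment: %s  transition: %s",
                     chargeSet@pigmentId, chargeSet@transition), con)
  writeLines("atom_name\tcharge_e", con)
  writeLines(sprintf("%s\t%.10g", chargeSet@atomNames, chargeSet@charges),
             con)
  invisible(path)
}

setMethod("show", "PigmentChargeSet", function(object) {
  cat("PigmentChargeSet:", object@pigmentId,
      sprintf("(%s)", object@transition), "-", length(object@charges),
      "atoms, net charge", format(sum(object@charges)), "e\n")
  invisible(NULL)
})

# deterministic TSV writer: fixed %.10g numeric formatting so reruns are
# byte-identical
writeTSV <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.10g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
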