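#' ProteinStructure: atoms of one chain of a PDB entry
#'
#' Thin container for the heavy-atom records of a chain of interest, as
#' needed by the residue-contact analysis. Coordinates are in Angstrom;
#' residue indices follow the numbering in the file (pVHL structures use the
#' full-length pVHL30 numbering).
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{element}, \code{x}, \code{y},
#'   \code{z}.
#' @slot chain character; the chain of interest.
#' @seealso [readStructure()], [detectContacts()]
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", chain = "character"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  if (nrow(a) && !all(is.finite(c(a$x, a$y, a$z))))
    return("coordinates must be finite")
  TRUE
})

#' Read a protein structure from a PDB file
#'
#' Loads the ATOM records of the requested chain (first model only), drops
#' waters and hydrogens, and resolves alternate locations to the highest
#' occupancy. Parsing is delegated to \code{bio3d}.
#'
#' @param path PDB file.
#' @param chain chain identifier; default takes the first chain present.
#' @return a [ProteinStructure-class].
#' @export
readStructure <- function(path, chain = NULL) {
  .assertFile(path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM" & !(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!nrow(a)) .err("vhlG2P_input_error", "no ATOM records in ", path)
  if (is.null(chain)) chain <- a$chain[1]
  if (!chain %in% a$chain)
    .err("vhlG2P_input_error", "unknown chain '", chain, "' in ", path)
  a <- a[a$chain == chain, , drop = FALSE]
  # alternate locations: keep the highest-occupancy record per atom
  if (any(!a$alt %in% c("", " ", NA))) {
    key <- paste(a$resno, a$elety)
    occ <- ifelse(is.na(a$o), 1, a$o)
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(i)
      i[which.max(occ[i])]), use.names = FALSE)
    a <- a[sort(keep), , drop = FALSE]
  }
  ele <- a$elesy
  if (is.null(ele) || all(is.na(ele)) || all(!nzchar(trimws(ele))))
    ele <- substr(trimws(a$elety), 1L, 1L)
  ele <- toupper(trimws(ele))
  heavy <- ele != "H"
  atoms <- data.frame(chain = a$chain, resno = as.integer(a$resno),
                      resid = a$resid, elety = trimws(a$elety),
                      element = ele, x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)[heavy, , drop = FALSE]
  rownames(atoms) <- NULL
  new("ProteinStructure", atoms = atoms, chain = chain)
}

#' Construct a ProteinStructure from an atom table
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{element}, \code{x}, \code{y}, \code{z}.
#' @param chain chain of interest (defaults to the first).
#' @return a [ProteinStructure-class].
#' @export
ProteinStructure <- function(atoms, chain = atoms$chain[1]) {
  new("ProteinStructure", atoms = atoms, chain = chain)
}

#' Atom table accessor
#' @param x a [ProteinStructure-class].
#' @export
structureAtoms <- function(x) x@atoms

#' Residues present in a structure
#' @param x a [ProteinStructure-class].
#' @return data.frame with columns \code{resno}, \code{resid}, one row per
#'   residue in file order.
#' @export
structureResidues <- function(x) {
  a <- x@atoms
  u <- !duplicated(paste(a$chain, a$resno))
  data.frame(resno = a$resno[u], resid = a$resid[u], stringsAsFactors = FALSE)
}

setMethod("show", "ProteinStructure", function(object) {
  r <- structureResidues(object)
  cat("ProteinStructure: chain", object@chain, "|", nrow(r), "residues |",
      nrow(object@atoms), "heavy atoms\n")
  invisible(NULL)
})

# minimal fixed-width PDB writer used by the toy-structure generators
.writePDB <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, atoms$elety[i], atoms$resid[i], atoms$chain[i],
            atoms$resno[i], atoms$x[i], atoms$y[i], atoms$z[i],
            atoms$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
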