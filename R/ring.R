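# Typed residue-contact detection from coordinates: a deliberately simple,
# fully-documented geometry (distance cutoffs only, no angle terms), in the
# spirit of residue-interaction-network tools. All cutoffs are exposed and
# recorded in every output.

# charged side-chain atoms (salt-bridge donors/acceptors)
.POS_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                   HIS = c("ND1", "NE2"))
.NEG_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# aromatic ring atoms for pi-pi centroid computation
.RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

# van der Waals radii by element (Angstrom)
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Default geometry cutoffs for contact typing
#'
#' Salt bridge: opposite-charge side-chain N/O pair within 4.0 A. Hydrogen
#' bond: donor/acceptor heavy-atom (N/O) pair within 3.5 A, no angle term.
#' van der Waals: heavy-atom pair within the sum of element radii plus a
#' 0.5 A tolerance. Pi-pi stacking: aromatic ring centroids (Phe/Tyr/Trp/His)
#' within 6.5 A. Per residue pair the highest-priority type is kept:
#' salt_bridge > hbond > pipi > vdw.
#'
#' @return named list of cutoffs.
#' @export
contactParams <- function() {
  list(salt_bridge = 4.0, hbond = 3.5, vdw_tolerance = 0.5, pipi = 6.5)
}

#' Build a typed residue-residue interaction network from coordinates
#'
#' Detects residue-residue contacts in a structure and types each residue
#' pair with the highest-priority interaction it realizes (salt_bridge >
#' hbond > pipi > vdw), recording the atom pair and distance. Sequence
#' -adjacent pairs (|i - j| < 2) are excluded within a chain to avoid
#' trivial backbone contacts. Residues lacking side-chain atoms simply
#' cannot realize the typed interactions and degrade to vdW contacts.
#'
#' @param structure a [ProteinStructure-class].
#' @param params cutoffs as from [contactParams()]; any subset can be
#'   overridden.
#' @return a [ResidueInteractionNetwork-class].
#' @examples
#' \dontrun{
#' net <- detectContacts(readStructure("1lm8.pdb", chain = "V"))
#' }
#' @export
detectContacts <- function(structure, params = contactParams()) {
  p <- utils::modifyList(contactParams(), params)
  a <- structureAtoms(structure)
  if (!nrow(a)) .err("vhlG2P_input_error", "empty structure")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rkey <- paste(a$chain, a$resno)
  radii <- .VDW_RADII[a$element]
  radii[is.na(radii)] <- 1.70
  maxAtomCut <- max(p$salt_bridge, p$hbond, 2 * max(radii) + p$vdw_tolerance)

  d2 <- .pairDist2(xyz)
  n <- nrow(a)
  cand <- which(upper.tri(d2) & d2 <= maxAtomCut^2, arr.ind = TRUE)
  edges <- list()
  if (nrow(cand)) {
    i <- cand[, 1]; j <- cand[, 2]
    sameRes <- rkey[i] == rkey[j]
    intra <- a$chain[i] == a$chain[j]
    adjacent <- intra & abs(a$resno[i] - a$resno[j]) < 2L
    ok <- !sameRes & !adjacent
    i <- i[ok]; j <- j[ok]
    dd <- sqrt(d2[cbind(i, j)])

    isPos <- .chargedAtom(a, .POS_ATOMS)
    isNeg <- .chargedAtom(a, .NEG_ATOMS)
    isNO <- a$element %in% c("N", "O")

    saltOK <- ((isPos[i] & isNeg[j]) | (isNeg[i] & isPos[j])) &
      dd <= p$salt_bridge
    hbOK <- isNO[i] & isNO[j] & dd <= p$hbond
    vdwOK <- dd <= radii[i] + radii[j] + p$vdw_tolerance

    edges$atomic <- data.frame(
      ai = i, aj = j, distance = dd,
      salt = saltOK, hb = hbOK, vdw = vdwOK, stringsAsFactors = FALSE)
  }

  rings <- .ringCentroids(a)
  pipi <- NULL
  if (nrow(rings) > 1L) {
    rd2 <- .pairDist2(as.matrix(rings[, c("x", "y", "z")]))
    rc <- which(upper.tri(rd2) & rd2 <= p$pipi^2, arr.ind = TRUE)
    if (nrow(rc)) {
      ri <- rc[, 1]; rj <- rc[, 2]
      same <- rings$key[ri] == rings$key[rj]
      adj <- rings$chain[ri] == rings$chain[rj] &
        abs(rings$resno[ri] - rings$resno[rj]) < 2L
      ok <- !same & !adj
      if (any(ok))
        pipi <- data.frame(ri = ri[ok], rj = rj[ok],
                           distance = sqrt(rd2[cbind(ri[ok], rj[ok])]))
    }
  }

  # collapse atom-level hits to one typed edge per residue pair
  best <- new.env(parent = emptyenv())
  put <- function(key, rec) {
    old <- best[[key]]
    if (is.null(old) || rec$priority < old$priority ||
        (rec$priority == old$priority && rec$distance < old$distance))
      best[[key]] <- rec
  }
  pairKey <- function(c1, r1, c2, r2) {
    if (c1 < c2 || (c1 == c2 && r1 < r2)) paste(c1, r1, c2, r2, sep = "|")
    else paste(c2, r2, c1, r1, sep = "|")
  }
  if (!is.null(edges$atomic) && nrow(edges$atomic)) {
    e <- edges$atomic
    type <- ifelse(e$salt, "salt_bridge",
                   ifelse(e$hb, "hbond", ifelse(e$vdw, "vdw", NA)))
    prio <- c(salt_bridge = 1L, hbond = 2L, vdw = 4L)
    for (k in which(!is.na(type))) {
      ai <- e$ai[k]; aj <- e$aj[k]
      key <- pairKey(a$chain[ai], a$resno[ai], a$chain[aj], a$resno[aj])
      ord <- a$chain[ai] < a$chain[aj] ||
        (a$chain[ai] == a$chain[aj] && a$resno[ai] < a$resno[aj])
      put(key, list(priority = prio[[type[k]]], type = type[k],
                    distance = e$distance[k],
                    atom_i = if (ord) a$elety[ai] else a$elety[aj],
                    atom_j = if (ord) a$elety[aj] else a$elety[ai],
                    chain_i = if (ord) a$chain[ai] else a$chain[aj],
                    chain_j = if (ord) a$chain[aj] else a$chain[ai],
                    res_i = if (ord) a$resno[ai] else a$resno[aj],
                    res_j = if (ord) a$resno[aj] else a$resno[ai]))
    }
  }
  if (!is.null(pipi)) {
    for (k in seq_len(nrow(pipi))) {
      ri <- pipi$ri[k]; rj <- pipi$rj[k]
      key <- pairKey(rings$chain[ri], rings$resno[ri],
                     rings$chain[rj], rings$resno[rj])
      ord <- rings$chain[ri] < rings$chain[rj] ||
        (rings$chain[ri] == rings$chain[rj] && rings$resno[ri] < rings$resno[rj])
      put(key, list(priority = 3L, type = "pipi", distance = pipi$distance[k],
                    atom_i = "RING", atom_j = "RING",
                    chain_i = if (ord) rings$chain[ri] else rings$chain[rj],
                    chain_j = if (ord) rings$chain[rj] else rings$chain[ri],
                    res_i = if (ord) rings$resno[ri] else rings$resno[rj],
                    res_j = if (ord) rings$resno[rj] else rings$resno[ri]))
    }
  }

  keys <- ls(best)
  edf <- if (length(keys)) {
    do.call(rbind, lapply(keys, function(k) {
      r <- best[[k]]
      data.frame(residue_i = r$res_i, residue_j = r$res_j,
                 contact_type = r$type, distance = r$distance,
                 atom_i = r$atom_i, atom_j = r$atom_j,
                 chain_i = r$chain_i, chain_j = r$chain_j,
                 chain_scope = if (r$chain_i == r$chain_j) "intra" else "inter",
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(residue_i = integer(), residue_j = integer(),
               contact_type = character(), distance = numeric(),
               atom_i = character(), atom_j = character(),
               chain_i = character(), chain_j = character(),
               chain_scope = character(), stringsAsFactors = FALSE)
  }
  if (nrow(edf)) {
    edf <- edf[order(edf$residue_i, edf$residue_j), , drop = FALSE]
    rownames(edf) <- NULL
  }
  nodes <- structureResidues(structure)
  new("ResidueInteractionNetwork", nodes = nodes, edges = edf, params = p)
}

.pairDist2 <- function(xyz) {
  s <- rowSums(xyz^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  d2
}

.chargedAtom <- function(a, map) {
  out <- logical(nrow(a))
  for (res in names(map)) out <- out | (a$resid == res & a$elety %in% map[[res]])
  out
}

.ringCentroids <- function(a) {
  out <- list()
  for (res in names(.RING_ATOMS)) {
    sub <- a[a$resid == res, , drop = FALSE]
    if (!nrow(sub)) next
    for (key in unique(paste(sub$chain, sub$resno))) {
      r <- sub[paste(sub$chain, sub$resno) == key, , drop = FALSE]
      ring <- r[r$elety %in% .RING_ATOMS[[res]], , drop = FALSE]
      if (nrow(ring) >= 4L)  # need most of the ring to place a centroid
        out[[length(out) + 1L]] <- data.frame(
          chain = ring$chain[1], resno = ring$resno[1], key = key,
          x = mean(ring$x), y = mean(ring$y), z = mean(ring$z),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chain = character(), resno = integer(),
                      key = character(), x = numeric(), y = numeric(),
                      z = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Contacts a substitution at one position could remove
#'
#' Returns every edge of the network incident to the given residue
#' position; an absent or isolated position yields an empty edge table.
#'
#' @param network a [ResidueInteractionNetwork-class].
#' @param position 1-based residue position.
#' @return data.frame of incident edges (same columns as the network's edge
#'   table).
#' @export
mutationEdgeImpact <- function(network, position) {
  e <- network@edges
  e[e$residue_i == position | e$residue_j == position, , drop = FALSE]
}

#' Edge table accessor
#' @param x a [ResidueInteractionNetwork-class].
#' @export
contactEdges <- function(x) x@edges

#' Geometry parameters accessor
#' @param x a [ResidueInteractionNetwork-class].
#' @export
contactParameters <- function(x) x@params

setMethod("show", "ResidueInteractionNetwork", function(object) {
  cat("ResidueInteractionNetwork:", nrow(object@nodes), "residues,",
      nrow(object@edges), "typed edges\n")
  if (nrow(object@edges)) {
    tt <- table(object@edges$contact_type)
    cat("  ", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Write a contact edge list as TSV
#'
#' Emits residue_i, residue_j, contact_type, distance and the atom pair,
#' with a commented header recording the geometry cutoffs used.
#'
#' @param x a [ResidueInteractionNetwork-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(x, path) {
  hdr <- paste0("# vhlG2P contact edges; cutoffs: ",
                paste(names(x@params), unlist(x@params), sep = "=",
                      collapse = ", "))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    x@edges[, c("residue_i", "residue_j", "contact_type", "distance",
                "atom_i", "atom_j")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Convert a contact network to an igraph graph
#'
#' @param x a [ResidueInteractionNetwork-class].
#' @return an undirected \code{igraph} graph with \code{contact_type} and
#'   \code{distance} edge attributes.
#' @export
asIgraph <- function(x) {
  nodes <- data.frame(name = as.character(x@nodes$resno),
                      resid = x@nodes$resid, stringsAsFactors = FALSE)
  e <- x@edges
  edges <- data.frame(from = as.character(e$residue_i),
                      to = as.character(e$residue_j),
                      contact_type = e$contact_type,
                      distance = e$distance, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export a contact network as GraphML
#'
#' @param x a [ResidueInteractionNetwork-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
exportGraphML <- function(x, path) {
  igraph::write_graph(asIgraph(x), path, format = "graphml")
  invisible(path)
}
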