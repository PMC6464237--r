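#' @import methods
NULL

#' MutationSet: a curated table of pVHL disease variants
#'
#' Container for manually-curated protein-level variants of the von
#' Hippel-Lindau tumor suppressor. Each variant carries its HGVS p. label,
#' the 1-based position on full-length pVHL30 (residues 1-213), wild-type and
#' mutant one-letter amino acids, the number of affected patients reported in
#' the literature, and a set of normalized phenotype terms.
#'
#' @slot variants data.frame with columns \code{variant}, \code{position},
#'   \code{wt_aa}, \code{mut_aa}, \code{synonymous}, \code{n_patients},
#'   \code{source_id}.
#' @slot phenotypes list of character vectors, parallel to the rows of
#'   \code{variants}; each element holds the normalized phenotype terms of
#'   that variant (possibly empty).
#' @slot log character vector of normalization messages (e.g. raw phenotype
#'   labels that fell through to \code{"other"}).
#'
#' @seealso [readMutationTable()], [normalizePhenotype()],
#'   [filterSinglePhenotype()]
#' @export
setClass("MutationSet",
  representation(variants = "data.frame", phenotypes = "list",
                 log = "character"),
  prototype(variants = emptyVariantFrame(), phenotypes = list(),
            log = character()))

setValidity("MutationSet", function(object) {
  v <- object@variants
  need <- c("variant", "position", "wt_aa", "mut_aa", "synonymous",
            "n_patients", "source_id")
  miss <- setdiff(need, names(v))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(v) != length(object@phenotypes))
    return("phenotypes list must be parallel to variant rows")
  if (nrow(v) == 0L) return(TRUE)
  if (any(v$position < 1L)) return("positions must be >= 1")
  if (any(v$n_patients < 0L)) return("patient counts must be >= 0")
  bad <- !v$synonymous & v$wt_aa == v$mut_aa
  if (any(bad))
    return(paste("wt and mutant residue identical for non-synonymous variant:",
                 paste(v$variant[bad], collapse = ", ")))
  vocab <- c(phenotypeVocabulary(), NA_character_)
  terms <- unique(unlist(object@phenotypes, use.names = FALSE))
  if (length(terms) && !all(terms %in% vocab))
    return(paste("phenotype terms outside the controlled vocabulary:",
                 paste(setdiff(terms, vocab), collapse = ", ")))
  TRUE
})

#' SurfaceSet: named binding-interface residue sets
#'
#' The pVHL binding surfaces used throughout the analysis: A (Elongin/VCB
#' assembly), B (HIF-1alpha substrate site), C (Cullin-2 side), D (the
#' pVHL30-specific N-terminal acidic tail) and E (C-terminal tail). Each
#' surface is a set of 1-based residue positions; surfaces may in principle
#' overlap.
#'
#' @slot surfaces named list of sorted integer vectors (residue positions).
#' @seealso [defaultSurfaces()], [readSurfaceConfig()], [assignSurface()]
#' @export
setClass("SurfaceSet", representation(surfaces = "list"))

setValidity("SurfaceSet", function(object) {
  s <- object@surfaces
  if (is.null(names(s)) || any(!nzchar(names(s))))
    return("every surface needs a name")
  if (anyDuplicated(names(s))) return("duplicated surface ids")
  for (id in names(s)) {
    r <- s[[id]]
    if (!length(r)) return(paste0("surface ", id, " is empty"))
    if (any(r < 1L) || anyDuplicated(r)) return(paste0("bad residues in surface ", id))
  }
  TRUE
})

#' PhenotypeDistribution: per-surface phenotype proportions
#'
#' Counts of single-phenotype variant records per phenotype term for one
#' binding surface (or \code{"overall"}), with proportions reported to one
#' decimal percent.
#'
#' @slot surfaceId character; a surface id or \code{"overall"}.
#' @slot counts named integer vector of record counts per phenotype term.
#' @slot nRecords integer; total records contributing.
#' @seealso [phenotypeDistribution()], [proportions()]
#' @export
setClass("PhenotypeDistribution",
  representation(surfaceId = "character", counts = "integer",
                 nRecords = "integer"))

setValidity("PhenotypeDistribution", function(object) {
  if (length(object@surfaceId) != 1L) return("surfaceId must be length 1")
  if (any(object@counts < 0L)) return("counts must be >= 0")
  if (sum(object@counts) != object@nRecords)
    return("counts must sum to nRecords")
  TRUE
})

#' ResidueInteractionNetwork: typed residue-residue contact graph
#'
#' Undirected graph of residue-residue contacts computed from atomic
#' coordinates, with each edge typed as \code{salt_bridge}, \code{hbond},
#' \code{pipi} or \code{vdw} (highest-priority type kept per residue pair)
#' and annotated with the realizing atom pair and distance in Angstrom.
#'
#' @slot nodes data.frame with columns \code{resno}, \code{resid}.
#' @slot edges data.frame with columns \code{residue_i}, \code{residue_j}
#'   (i < j), \code{contact_type}, \code{distance}, \code{atom_i},
#'   \code{atom_j}, \code{chain_scope}.
#' @slot params list of the geometry cutoffs used (recorded in every export).
#' @seealso [detectContacts()], [mutationEdgeImpact()]
#' @export
setClass("ResidueInteractionNetwork",
  representation(nodes = "data.frame", edges = "data.frame", params = "list"))

setValidity("ResidueInteractionNetwork", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(e$residue_i >= e$residue_j & e$chain_scope == "intra"))
      return("intra-chain edges must have residue_i < residue_j")
    if (any(e$distance <= 0)) return("distances must be positive")
    if (any(e$chain_scope == "intra" & abs(e$residue_j - e$residue_i) < 2L))
      return("sequence-adjacent intra-chain pairs are excluded")
  }
  TRUE
})

#' PetriNet: place/transition net for pathway simulation
#'
#' A discrete place/transition model of a signaling pathway. Arcs connect a
#' place to a transition or vice versa (bipartite), with positive integer
#' weights. Transitions listed in \code{disabled} are knocked out and never
#' fire.
#'
#' @slot places data.frame with columns \code{id}, \code{label}, \code{initial}.
#' @slot transitions data.frame with columns \code{id}, \code{label}.
#' @slot arcs data.frame with columns \code{from}, \code{to}, \code{weight}.
#' @slot disabled character vector of knocked-out transition ids.
#' @seealso [buildNet()], [simulateNet()], [knockout()]
#' @export
setClass("PetriNet",
  representation(places = "data.frame", transitions = "data.frame",
                 arcs = "data.frame", disabled = "character"))

setValidity("PetriNet", function(object) {
  p <- object@places; t <- object@transitions; a <- object@arcs
  if (anyDuplicated(c(p$id, t$id))) return("place/transition ids must be unique")
  if (nrow(p) && any(p$initial < 0L)) return("initial marking must be >= 0")
  if (nrow(a)) {
    if (any(a$weight < 1L)) return("arc weights must be >= 1")
    known <- c(p$id, t$id)
    dangling <- setdiff(c(a$from, a$to), known)
    if (length(dangling))
      return(paste("dangling arc endpoint(s):", paste(dangling, collapse = ", ")))
    pt <- a$from %in% p$id & a$to %in% t$id
    tp <- a$from %in% t$id & a$to %in% p$id
    if (!all(pt | tp))
      return("arcs must connect a place to a transition or vice versa")
  }
  if (length(object@disabled) && !all(object@disabled %in% t$id))
    return("disabled ids must name transitions")
  TRUE
})

#' PetriExperiment: summarized simulation result
#'
#' Per-place mean and standard deviation of final token counts over
#' replicates, per-transition firing counts, coarse trajectories, and an
#' echo of the simulation configuration (steps, replicates, seed, policy).
#'
#' @slot summary data.frame with columns \code{place}, \code{mean}, \code{sd}.
#' @slot firings data.frame with columns \code{transition}, \code{mean_count}.
#' @slot trajectories matrix of mean token counts, places x checkpoints.
#' @slot config list echoing the [SimulationConfig] used.
#' @seealso [simulateNet()], [compareExperiments()]
#' @export
setClass("PetriExperiment",
  representation(summary = "data.frame", firings = "data.frame",
                 trajectories = "matrix", config = "list"))

#' ImpairmentMatrix: phenotype x interactor conservation snapshot
#'
#' For each phenotype (rows) and interactor (columns), whether any mutation
#' from the phenotype's single-phenotype variant subset falls inside the
#' interactor's binding residues (\code{"affected"}) or none does
#' (\code{"unaffected"}, the "negative snapshot" of conserved interactions).
#'
#' @slot matrix character matrix with values "affected"/"unaffected",
#'   phenotype rows and alphabetical interactor columns.
#' @slot provenance list: per-phenotype mutation positions used.
#' @slot vacuous character; phenotypes whose row was computed from zero
#'   mutations (every interactor trivially unaffected).
#' @seealso [buildImpairmentMatrix()], [unaffectedInteractors()]
#' @export
setClass("ImpairmentMatrix",
  representation(matrix = "matrix", provenance = "list", vacuous = "character"))
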