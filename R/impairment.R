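#' Read an interactor table (TSV)
#'
#' Expected columns: \code{name} (gene symbol), \code{uniprot},
#' \code{binding_residues} (inclusive 1-based ranges, e.g. "54-113,157-171").
#' Lines starting with \code{#} are ignored.
#'
#' @param path TSV file.
#' @return data.frame with columns \code{name}, \code{uniprot} and a
#'   list-column \code{binding_residues} of integer vectors.
#' @export
readInteractorTable <- function(path) {
  .assertFile(path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(c("name", "uniprot", "binding_residues"), names(tab))
  if (length(miss))
    .err("vhlG2P_config_error", "missing column(s): ", paste(miss, collapse = ", "))
  tab$binding_residues <- lapply(tab$binding_residues, .parseRanges)
  tab
}

#' Read a PTM-site table (TSV)
#'
#' Expected columns: \code{position}, \code{type} (phosphorylation,
#' neddylation, sumoylation, methylation, ubiquitination), \code{enzyme}.
#'
#' @param path TSV file.
#' @param proteinLength upper bound for positions (default 213, pVHL30).
#' @return data.frame of PTM sites.
#' @export
readPTMTable <- function(path, proteinLength = 213L) {
  .assertFile(path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(c("position", "type", "enzyme"), names(tab))
  if (length(miss))
    .err("vhlG2P_config_error", "missing column(s): ", paste(miss, collapse = ", "))
  tab$position <- as.integer(tab$position)
  if (any(tab$position < 1L | tab$position > proteinLength))
    .err("vhlG2P_input_error", "PTM position outside the protein length")
  known <- c("phosphorylation", "neddylation", "sumoylation", "methylation",
             "ubiquitination")
  if (!all(tab$type %in% known))
    .err("vhlG2P_input_error", "unknown PTM type: ",
         paste(setdiff(tab$type, known), collapse = ", "))
  tab$enzyme <- as.character(tab$enzyme)
  bad <- tab$type == "phosphorylation" &
    (is.na(tab$enzyme) | !nzchar(trimws(tab$enzyme)))
  if (any(bad))
    .err("vhlG2P_input_error", "phosphorylation entries need an enzyme")
  tab
}

#' Interactors untouched by a phenotype's mutations
#'
#' The "negative snapshot": interactors whose binding residues contain none
#' of the mutation positions associated with the given phenotype. Input
#' records should be pre-filtered to single-phenotype variants of that
#' phenotype. A phenotype with zero records returns every interactor,
#' flagged vacuous.
#'
#' @param phenotype normalized phenotype term.
#' @param x a [MutationSet-class] of that phenotype's single-phenotype
#'   records.
#' @param interactors data.frame from [readInteractorTable()].
#' @param margin optional +/- residue halo around each mutation position
#'   (default 0: exact positional overlap).
#' @return character vector of unaffected interactor names; attribute
#'   \code{"vacuous"} is TRUE when computed from zero mutations.
#' @export
unaffectedInteractors <- function(phenotype, x, interactors, margin = 0L) {
  pos <- unique(mutationPositions(x))
  if (margin > 0L)
    pos <- unique(unlist(lapply(pos, function(p) (p - margin):(p + margin))))
  hit <- vapply(interactors$binding_residues,
                function(r) any(r %in% pos), logical(1))
  out <- sort(interactors$name[!hit])
  attr(out, "vacuous") <- length(pos) == 0L
  out
}

#' Build the phenotype x interactor impairment matrix
#'
#' One row per phenotype carrying at least one single-phenotype mutation;
#' columns in alphabetical interactor order. A cell is "unaffected" iff no
#' mutation position of that phenotype's subset falls in the interactor's
#' binding residues. Deterministic; reproducible bit-exactly.
#'
#' @param x a [MutationSet-class] (single-phenotype filtering is applied
#'   internally).
#' @param interactors data.frame from [readInteractorTable()].
#' @param phenotypes optional character vector restricting/ordering the
#'   rows; default: all phenotypes observed, vocabulary order.
#' @param groups optional named list mapping a row name to several
#'   vocabulary terms pooled into that row (e.g. one hemangioblastoma row
#'   pooling the cerebellar and retinal subtypes); overrides
#'   \code{phenotypes}.
#' @param margin passed to [unaffectedInteractors()].
#' @return an [ImpairmentMatrix-class].
#' @export
buildImpairmentMatrix <- function(x, interactors, phenotypes = NULL,
                                  groups = NULL, margin = 0L) {
  single <- filterSinglePhenotype(x)
  term <- vapply(single@phenotypes, `[[`, character(1), 1L)
  if (is.null(groups)) {
    if (is.null(phenotypes))
      phenotypes <- phenotypeVocabulary()[phenotypeVocabulary() %in% term]
    groups <- stats::setNames(as.list(phenotypes), phenotypes)
  }
  cols <- sort(interactors$name)
  mat <- matrix("unaffected", nrow = length(groups), ncol = length(cols),
                dimnames = list(names(groups), cols))
  prov <- list(); vac <- character()
  for (ph in names(groups)) {
    sub <- single[term %in% groups[[ph]]]
    un <- unaffectedInteractors(ph, sub, interactors, margin)
    mat[ph, setdiff(cols, un)] <- "affected"
    prov[[ph]] <- sort(unique(mutationPositions(sub)))
    if (isTRUE(attr(un, "vacuous"))) vac <- c(vac, ph)
  }
  new("ImpairmentMatrix", matrix = mat, provenance = prov, vacuous = vac)
}

#' Unaffected interactors of one matrix row
#' @param x an [ImpairmentMatrix-class].
#' @param phenotype row name.
#' @return character vector of interactor names left unaffected.
#' @export
unaffectedRow <- function(x, phenotype) {
  if (!phenotype %in% rownames(x@matrix))
    .err("vhlG2P_input_error", "no such phenotype row: ", phenotype)
  sort(colnames(x@matrix)[x@matrix[phenotype, ] == "unaffected"])
}

#' Impairment matrix accessor
#' @param x an [ImpairmentMatrix-class].
#' @return character matrix of "affected"/"unaffected" cells.
#' @export
impairmentCells <- function(x) x@matrix

setMethod("show", "ImpairmentMatrix", function(object) {
  m <- object@matrix
  cat("ImpairmentMatrix:", nrow(m), "phenotypes x", ncol(m), "interactors\n")
  for (ph in rownames(m)) {
    un <- colnames(m)[m[ph, ] == "unaffected"]
    cat(sprintf("  %-28s unaffected: %s\n", ph,
                if (length(un)) paste(un, collapse = ", ") else "(none)"))
  }
  if (length(object@vacuous))
    cat("  vacuous rows (no mutations):",
        paste(object@vacuous, collapse = ", "), "\n")
  invisible(NULL)
})

#' Write an impairment matrix as TSV
#'
#' Cells are abbreviated A (affected) / U (unaffected); a commented header
#' records the tool version.
#'
#' @param x an [ImpairmentMatrix-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeImpairmentMatrix <- function(x, path) {
  m <- ifelse(x@matrix == "affected", "A", "U")
  hdr <- paste0("# vhlG2P ", as.character(utils::packageVersion("vhlG2P")),
                " impairment matrix (A=affected, U=unaffected)")
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    data.frame(phenotype = rownames(m), m, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}

#' PTM sites overlapped by missense mutations
#'
#' Reports every PTM site whose position carries at least one missense
#' mutation, with the overlapping variants and the union of their
#' phenotypes.
#'
#' @param x a [MutationSet-class]; synonymous records are ignored.
#' @param sites data.frame from [readPTMTable()].
#' @return data.frame with one row per overlapped site: \code{position},
#'   \code{ptm_type}, \code{enzyme}, \code{variants} (comma-separated),
#'   \code{phenotypes} (comma-separated union).
#' @export
ptmOverlap <- function(x, sites) {
  x <- dropSynonymous(x)
  pos <- mutationPositions(x)
  out <- lapply(seq_len(nrow(sites)), function(i) {
    hit <- which(pos == sites$position[i])
    if (!length(hit)) return(NULL)
    data.frame(position = sites$position[i], ptm_type = sites$type[i],
               enzyme = sites$enzyme[i],
               variants = paste(sort(unique(x@variants$variant[hit])),
                                collapse = ","),
               phenotypes = paste(sort(unique(unlist(x@phenotypes[hit]))),
                                  collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(position = integer(), ptm_type = character(),
                      enzyme = character(), variants = character(),
                      phenotypes = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
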