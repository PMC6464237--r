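#' Parse an HGVS protein-level variant label
#'
#' Parses labels of the form \code{p.Arg167Trp} (missense) or
#' \code{p.Arg200=} (synonymous) into wild-type residue, 1-based position and
#' mutant residue on the full-length pVHL30 numbering. DNA-level (c.)
#' notation is not supported.
#'
#' @param label character vector of HGVS p. labels.
#' @return data.frame with columns \code{wt_aa}, \code{position},
#'   \code{mut_aa} (\code{"="} for synonymous), \code{synonymous}; rows that
#'   fail to parse carry NA in all fields.
#' @examples
#' parseHGVS("p.Arg167Trp")
#' @export
parseHGVS <- function(label) {
  label <- trimws(label)
  pat <- "^p\\.([A-Z][a-z]{2})([0-9]+)(=|[A-Z][a-z]{2})$"
  m <- regmatches(label, regexec(pat, label))
  one <- function(tok) unname(.AA321[tok])
  parsed <- lapply(m, function(g) {
    if (length(g) != 4L) return(NULL)
    wt <- one(g[2])
    mut <- if (g[4] == "=") "=" else one(g[4])
    if (is.na(wt) || is.na(mut)) return(NULL)
    list(wt = wt, pos = as.integer(g[3]), mut = mut)
  })
  ok <- !vapply(parsed, is.null, logical(1))
  data.frame(
    wt_aa = ifelse(ok, vapply(parsed, function(p) if (is.null(p)) NA_character_ else p$wt, character(1)), NA_character_),
    position = ifelse(ok, vapply(parsed, function(p) if (is.null(p)) NA_integer_ else p$pos, integer(1)), NA_integer_),
    mut_aa = ifelse(ok, vapply(parsed, function(p) if (is.null(p)) NA_character_ else p$mut, character(1)), NA_character_),
    synonymous = ifelse(ok, vapply(parsed, function(p) if (is.null(p)) NA else identical(p$mut, "="), logical(1)), NA),
    stringsAsFactors = FALSE)
}

#' Default phenotype synonym map
#'
#' Case-insensitive mapping from raw literature labels to the controlled
#' vocabulary ([phenotypeVocabulary()]). Shipped as an editable YAML config;
#' renal manifestations (ccRCC, RCC, renal cysts, renal carcinoma) collapse
#' into \code{renal_disease}.
#'
#' @param path optional path to a YAML file mapping term -> list of raw
#'   labels; defaults to the packaged config.
#' @return named character vector: lower-cased raw label -> vocabulary term.
#' @export
phenotypeSynonyms <- function(path = system.file("extdata", "phenotype_synonyms.yaml",
                                                 package = "vhlG2P")) {
  .assertFile(path)
  cfg <- yaml::read_yaml(path)
  out <- unlist(lapply(names(cfg), function(term) {
    stats::setNames(rep(term, length(cfg[[term]])), tolower(cfg[[term]]))
  }))
  bad <- setdiff(unique(out), phenotypeVocabulary())
  if (length(bad))
    .err("vhlG2P_config_error", "synonym map targets outside vocabulary: ",
         paste(bad, collapse = ", "))
  out
}

#' Normalize a raw phenotype label to the controlled vocabulary
#'
#' Deterministic, case-insensitive mapping; e.g. "ccRCC", "RCC", "renal
#' cysts" and "renal carcinoma" all map to \code{renal_disease}. Labels not
#' present in the synonym map fall through to \code{other}.
#'
#' @param raw character vector of raw labels.
#' @param synonyms named map as returned by [phenotypeSynonyms()].
#' @return character vector of vocabulary terms, with attribute
#'   \code{"unmapped"} listing labels that fell through to \code{other}.
#' @examples
#' normalizePhenotype(c("ccRCC", "Renal cysts", "PHEOCHROMOCYTOMA"))
#' @export
normalizePhenotype <- function(raw, synonyms = phenotypeSynonyms()) {
  key <- tolower(trimws(raw))
  hit <- synonyms[key]
  vocab <- phenotypeVocabulary()
  # already-normalized terms are fixed points
  direct <- key %in% vocab
  out <- ifelse(direct, key, unname(hit))
  unmapped <- unique(raw[is.na(out) & nzchar(key)])
  out[is.na(out)] <- "other"
  attr(out, "unmapped") <- unmapped
  out
}

#' Construct a MutationSet from parsed fields
#'
#' Low-level constructor; most users will call [readMutationTable()].
#'
#' @param variant HGVS p. labels.
#' @param position integer positions (1-based, pVHL30 numbering).
#' @param wt_aa,mut_aa one-letter residues (\code{"="} for synonymous mutant).
#' @param n_patients non-negative integer patient counts.
#' @param phenotypes list of character vectors of normalized terms.
#' @param source_id provenance text.
#' @param log normalization log messages.
#' @return a [MutationSet-class] object.
#' @export
MutationSet <- function(variant, position, wt_aa, mut_aa, n_patients,
                        phenotypes = rep(list(character()), length(variant)),
                        source_id = rep(NA_character_, length(variant)),
                        log = character()) {
  v <- data.frame(variant = as.character(variant),
                  position = as.integer(position),
                  wt_aa = as.character(wt_aa),
                  mut_aa = as.character(mut_aa),
                  synonymous = as.character(mut_aa) == "=",
                  n_patients = as.integer(n_patients),
                  source_id = as.character(source_id),
                  stringsAsFactors = FALSE)
  new("MutationSet", variants = v, phenotypes = phenotypes, log = log)
}

#' Read a curated mutation table (TSV)
#'
#' Expected columns: \code{variant} (HGVS p.), \code{n_patients},
#' \code{phenotypes} (semicolon-separated raw labels), \code{source}.
#' Column names can be remapped via \code{dialect}. Rows whose HGVS token
#' fails to parse are collected into the parse-error report (attribute and
#' \code{mutationLog()}), never silently dropped. Lines starting with
#' \code{#} are ignored.
#'
#' @param path TSV file path.
#' @param dialect named character vector remapping required names to actual
#'   column names, e.g. \code{c(variant = "HGVS")}.
#' @param synonyms phenotype synonym map (see [phenotypeSynonyms()]).
#' @return a [MutationSet-class]; attribute \code{"errors"} holds a
#'   data.frame of failed rows (line, variant, reason).
#' @export
readMutationTable <- function(path, dialect = character(),
                              synonyms = phenotypeSynonyms()) {
  .assertFile(path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c(variant = "variant", n_patients = "n_patients",
            phenotypes = "phenotypes", source = "source")
  need[names(dialect)] <- dialect
  miss <- setdiff(unname(need), names(tab))
  if (length(miss))
    .err("vhlG2P_config_error", "missing required column(s): ",
         paste(miss, collapse = ", "))
  hg <- parseHGVS(tab[[need["variant"]]])
  bad <- is.na(hg$position)
  errors <- data.frame(line = which(bad) + 1L,
                       variant = tab[[need["variant"]]][bad],
                       reason = rep("malformed HGVS token", sum(bad)),
                       stringsAsFactors = FALSE)
  keep <- !bad
  rawPheno <- strsplit(as.character(tab[[need["phenotypes"]]][keep]), ";", fixed = TRUE)
  logs <- character()
  phen <- lapply(rawPheno, function(p) {
    p <- trimws(p[nzchar(trimws(p))])
    if (!length(p)) return(character())
    norm <- normalizePhenotype(p, synonyms)
    un <- attr(norm, "unmapped")
    if (length(un))
      logs <<- c(logs, paste0("unknown phenotype label mapped to other: ", un))
    sort(unique(as.character(norm)))
  })
  ms <- MutationSet(variant = tab[[need["variant"]]][keep],
                    position = hg$position[keep],
                    wt_aa = hg$wt_aa[keep], mut_aa = hg$mut_aa[keep],
                    n_patients = tab[[need["n_patients"]]][keep],
                    phenotypes = phen,
                    source_id = as.character(tab[[need["source"]]][keep]),
                    log = unique(logs))
  attr(ms, "errors") <- errors
  ms
}

#' Write a mutation table (TSV)
#'
#' Emits the columns read by [readMutationTable()] plus a commented header
#' line recording tool version and parameters, so read/write round-trips are
#' field-identical.
#'
#' @param x a [MutationSet-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMutationTable <- function(x, path) {
  stopifnot(is(x, "MutationSet"))
  v <- x@variants
  out <- data.frame(variant = v$variant,
                    n_patients = v$n_patients,
                    phenotypes = vapply(x@phenotypes, paste, character(1),
                                        collapse = ";"),
                    source = v$source_id,
                    stringsAsFactors = FALSE)
  hdr <- paste0("# vhlG2P ", as.character(utils::packageVersion("vhlG2P")),
                " mutation table; n=", nrow(out))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(out, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Keep only variants associated with a single phenotype
#'
#' Filters to records whose normalized phenotype set has cardinality one.
#' Because normalization collapses renal manifestations, a raw set like
#' \{ccRCC, renal cysts\} reduces to \{renal_disease\} and passes the filter.
#' Idempotent; output is always a subset of the input.
#'
#' @param x a [MutationSet-class] (phenotypes already normalized).
#' @return a [MutationSet-class] restricted to single-phenotype records.
#' @export
filterSinglePhenotype <- function(x) {
  stopifnot(is(x, "MutationSet"))
  keep <- vapply(x@phenotypes, function(p) length(unique(p)) == 1L, logical(1))
  new("MutationSet", variants = x@variants[keep, , drop = FALSE],
      phenotypes = x@phenotypes[keep], log = x@log)
}

#' Drop synonymous variants
#'
#' Synonymous records (mutant \code{"="}) are retained by the parser but
#' excluded from surface/phenotype statistics by default.
#'
#' @param x a [MutationSet-class].
#' @return a [MutationSet-class] with synonymous rows removed.
#' @export
dropSynonymous <- function(x) {
  stopifnot(is(x, "MutationSet"))
  keep <- !x@variants$synonymous
  new("MutationSet", variants = x@variants[keep, , drop = FALSE],
      phenotypes = x@phenotypes[keep], log = x@log)
}

# ---- accessors ----

#' @describeIn MutationSet-class number of variant records.
#' @param x a MutationSet.
#' @export
setMethod("length", "MutationSet", function(x) nrow(x@variants))

#' Variant table accessor
#' @param x a [MutationSet-class].
#' @return data.frame of variant fields (no phenotypes).
#' @export
mutationTable <- function(x) x@variants

#' Positions of all variant records
#' @param x a [MutationSet-class].
#' @return integer vector, one entry per record.
#' @export
mutationPositions <- function(x) x@variants$position

#' Patient counts of all variant records
#' @param x a [MutationSet-class].
#' @return integer vector, one entry per record.
#' @export
patientCounts <- function(x) x@variants$n_patients

#' Phenotype sets of all variant records
#' @param x a [MutationSet-class].
#' @return list of character vectors of normalized terms.
#' @export
mutationPhenotypes <- function(x) x@phenotypes

#' Normalization log accessor
#' @param x a [MutationSet-class].
#' @return character vector of log messages.
#' @export
mutationLog <- function(x) x@log

#' @export
setMethod("[", "MutationSet", function(x, i, j, ..., drop = TRUE) {
  new("MutationSet", variants = x@variants[i, , drop = FALSE],
      phenotypes = x@phenotypes[i], log = x@log)
})

setMethod("show", "MutationSet", function(object) {
  v <- object@variants
  cat("MutationSet with", nrow(v), "variant records\n")
  if (nrow(v)) {
    cat("  positions:", min(v$position), "-", max(v$position),
        "| patients total:", sum(v$n_patients),
        "| synonymous:", sum(v$synonymous), "\n")
    terms <- sort(table(unlist(object@phenotypes)), decreasing = TRUE)
    if (length(terms))
      cat("  top phenotypes:",
          paste(utils::head(names(terms), 4), collapse = ", "), "\n")
  }
  invisible(NULL)
})
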