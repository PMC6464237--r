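#' Construct a SurfaceSet
#'
#' @param surfaces named list of integer residue vectors (1-based).
#' @return a [SurfaceSet-class].
#' @export
SurfaceSet <- function(surfaces) {
  surfaces <- lapply(surfaces, function(r) sort(unique(as.integer(r))))
  new("SurfaceSet", surfaces = surfaces)
}

#' Read a surface-definition config (YAML or JSON)
#'
#' The config maps surface id to a list of inclusive 1-based ranges, e.g.
#' \code{A: ["156-190"]}. Ranges may be given as "a-b" strings or single
#' positions.
#'
#' @param path YAML (.yaml/.yml) or JSON file.
#' @return a [SurfaceSet-class].
#' @export
readSurfaceConfig <- function(path) {
  .assertFile(path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  SurfaceSet(lapply(cfg, function(ranges)
    unlist(lapply(as.character(ranges), .parseRanges))))
}

#' Default pVHL binding-surface definitions
#'
#' Packaged reconstruction of the five pVHL binding surfaces on the
#' full-length pVHL30 numbering (1-213): D = N-terminal acidic tail (59
#' residues, pVHL30-specific), B = HIF-1alpha substrate interface (43), C =
#' Cullin-2 side (49), A = Elongin/VCB interface (35), E = C-terminal tail
#' (23). Exact residue memberships are a documented best-effort
#' reconstruction (the interface literature defines them structurally);
#' sizes match the denominators used in the normalized mutated-fraction
#' analysis, and every residue named in the genotype-phenotype narrative
#' falls on its expected surface.
#'
#' @return a [SurfaceSet-class].
#' @export
defaultSurfaces <- function() {
  readSurfaceConfig(system.file("extdata", "surfaces.yaml", package = "vhlG2P"))
}

#' Surface ids of a SurfaceSet
#' @param x a [SurfaceSet-class].
#' @export
surfaceIDs <- function(x) names(x@surfaces)

#' Residues of one surface
#' @param x a [SurfaceSet-class].
#' @param id surface id.
#' @return sorted integer vector of 1-based residue positions.
#' @export
surfaceResidues <- function(x, id) {
  if (!id %in% names(x@surfaces))
    .err("vhlG2P_input_error", "unknown surface id: ", id)
  x@surfaces[[id]]
}

#' Sizes of all surfaces
#' @param x a [SurfaceSet-class].
#' @return named integer vector of surface sizes.
#' @export
surfaceSizes <- function(x) vapply(x@surfaces, length, integer(1))

setMethod("show", "SurfaceSet", function(object) {
  cat("SurfaceSet with", length(object@surfaces), "surfaces\n")
  for (id in names(object@surfaces)) {
    r <- object@surfaces[[id]]
    cat("  ", id, ": ", length(r), " residues (", .collapseRanges(r), ")\n",
        sep = "")
  }
  invisible(NULL)
})

#' Assign a residue position to binding surfaces
#'
#' @param position integer vector of 1-based positions.
#' @param surfaces a [SurfaceSet-class]; defaults to [defaultSurfaces()].
#' @return for a single position, a character vector of surface ids (empty
#'   if none); for several, a list of such vectors.
#' @examples
#' \dontrun{assignSurface(167)  # "A"}
#' @export
assignSurface <- function(position, surfaces = defaultSurfaces()) {
  one <- function(p) {
    ids <- names(surfaces@surfaces)[vapply(surfaces@surfaces,
                                           function(r) p %in% r, logical(1))]
    as.character(ids)
  }
  if (length(position) == 1L) one(position) else lapply(position, one)
}

#' Normalized mutated fraction of a binding surface
#'
#' Counts distinct mutated positions inside the surface and normalizes over
#' the number of residues forming the interface, reporting the percentage
#' rounded to the nearest integer (e.g. 39 mutated of 43 residues on the
#' HIF-binding surface gives 91\%). Invariant to duplicated records at the
#' same position.
#'
#' @param x a [MutationSet-class], restricted upstream to missense,
#'   phenotype-associated variants.
#' @param surfaces a [SurfaceSet-class].
#' @param id surface id to score.
#' @return data.frame with columns \code{surface_id},
#'   \code{n_mutated_positions}, \code{interface_size},
#'   \code{mutated_fraction_pct}.
#' @export
mutatedFraction <- function(x, surfaces = defaultSurfaces(), id) {
  res <- surfaceResidues(surfaces, id)
  if (!length(res)) .err("vhlG2P_input_error", "empty surface definition")
  nmut <- length(intersect(unique(mutationPositions(x)), res))
  data.frame(surface_id = id, n_mutated_positions = nmut,
             interface_size = length(res),
             mutated_fraction_pct = round(100 * nmut / length(res)),
             stringsAsFactors = FALSE)
}

#' Mutated fraction across all surfaces
#'
#' @inheritParams mutatedFraction
#' @return data.frame, one row per surface (see [mutatedFraction()]).
#' @export
surfaceMutationStats <- function(x, surfaces = defaultSurfaces()) {
  do.call(rbind, lapply(surfaceIDs(surfaces),
                        function(id) mutatedFraction(x, surfaces, id)))
}

#' Phenotype distribution of a surface (or overall)
#'
#' Proportion of single-phenotype variant records carrying each phenotype
#' term among the records whose position maps to the surface. Records
#' touching several surfaces count once per surface they touch (all-match
#' overlap policy). Zero records yield an empty distribution, not an error.
#'
#' @param x a [MutationSet-class] of single-phenotype records (apply
#'   [filterSinglePhenotype()] upstream).
#' @param surfaces a [SurfaceSet-class].
#' @param id surface id, or \code{"overall"} for all records.
#' @return a [PhenotypeDistribution-class].
#' @export
phenotypeDistribution <- function(x, surfaces = defaultSurfaces(),
                                  id = "overall") {
  if (identical(id, "overall")) {
    keep <- rep(TRUE, length(x))
  } else {
    res <- surfaceResidues(surfaces, id)
    keep <- mutationPositions(x) %in% res
  }
  terms <- vapply(x@phenotypes[keep], function(p) {
    if (length(p)) p[[1]] else NA_character_
  }, character(1))
  terms <- terms[!is.na(terms)]
  counts <- table(factor(terms, levels = phenotypeVocabulary()))
  counts <- counts[counts > 0L]
  new("PhenotypeDistribution", surfaceId = id,
      counts = stats::setNames(as.integer(counts), names(counts)),
      nRecords = length(terms))
}

#' Proportions of a PhenotypeDistribution
#'
#' @param x a [PhenotypeDistribution-class].
#' @param digits decimals for the reported percentages (default 1, matching
#'   the one-decimal reporting convention).
#' @return named numeric vector of percentages, descending.
#' @export
phenotypeProportions <- function(x, digits = 1) {
  if (x@nRecords == 0L) return(stats::setNames(numeric(), character()))
  sort(round(100 * x@counts / x@nRecords, digits), decreasing = TRUE)
}

#' Record count of a PhenotypeDistribution
#' @param x a [PhenotypeDistribution-class].
#' @export
nRecords <- function(x) x@nRecords

setMethod("show", "PhenotypeDistribution", function(object) {
  cat("PhenotypeDistribution [", object@surfaceId, "] over ",
      object@nRecords, " records\n", sep = "")
  p <- phenotypeProportions(object)
  for (i in seq_along(p))
    cat(sprintf("  %-28s %5.1f%%\n", names(p)[i], p[i]))
  invisible(NULL)
})

#' Test cross-surface differences
#'
#' Three methods are provided. \code{chi_square}: builds the surface x
#' phenotype contingency table of single-phenotype record counts and applies
#' the chi-squared test of independence (no continuity correction).
#' \code{permutation}: same statistic, null generated by shuffling surface
#' labels over records (seeded). \code{anova}: one-way ANOVA on per-position
#' mutation counts grouped by surface, the test used for differences in
#' mutation distribution across surfaces. Phenotype columns that are zero in
#' every group are dropped (logged via a message).
#'
#' @param dists list of [PhenotypeDistribution-class] objects with
#'   \code{nRecords > 0} (for \code{chi_square}/\code{permutation}).
#' @param method one of \code{"chi_square"}, \code{"permutation"},
#'   \code{"anova"}.
#' @param x,surfaces for \code{method = "anova"}: the [MutationSet-class]
#'   and [SurfaceSet-class] from which per-position counts are taken.
#' @param nPermutations,seed permutation-null settings.
#' @return data.frame with columns \code{comparison}, \code{statistic},
#'   \code{p_value}, \code{method}.
#' @export
compareSurfaces <- function(dists = NULL,
                            method = c("chi_square", "permutation", "anova"),
                            x = NULL, surfaces = defaultSurfaces(),
                            nPermutations = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (method == "anova") {
    if (is.null(x)) .err("vhlG2P_input_error", "anova needs a MutationSet")
    grp <- character(); cnt <- integer()
    pos <- mutationPositions(x)
    for (id in surfaceIDs(surfaces)) {
      res <- surfaceResidues(surfaces, id)
      percount <- vapply(res, function(r) sum(pos == r), integer(1))
      grp <- c(grp, rep(id, length(res))); cnt <- c(cnt, percount)
    }
    fit <- stats::aov(cnt ~ factor(grp))
    s <- summary(fit)[[1]]
    return(data.frame(comparison = paste(surfaceIDs(surfaces), collapse = ","),
                      statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
                      method = "anova", stringsAsFactors = FALSE))
  }
  dists <- Filter(function(d) d@nRecords > 0L, dists)
  if (length(dists) < 2L)
    .err("vhlG2P_input_error", "need >= 2 non-empty groups")
  terms <- sort(unique(unlist(lapply(dists, function(d) names(d@counts)))))
  tab <- t(vapply(dists, function(d) {
    v <- stats::setNames(rep(0L, length(terms)), terms)
    v[names(d@counts)] <- d@counts
    v
  }, integer(length(terms))))
  rownames(tab) <- vapply(dists, function(d) d@surfaceId, character(1))
  zero <- colSums(tab) == 0L
  if (any(zero)) {
    message("dropping all-zero phenotype column(s): ",
            paste(terms[zero], collapse = ", "))
    tab <- tab[, !zero, drop = FALSE]
  }
  cmp <- paste(rownames(tab), collapse = ",")
  if (identical(dim(tab), c(nrow(tab), 1L)) || nrow(tab) < 2L)
    .err("vhlG2P_input_error", "degenerate contingency table")
  obs <- .chisqStat(tab)
  if (method == "chi_square") {
    p <- stats::pchisq(obs, df = (nrow(tab) - 1L) * (ncol(tab) - 1L),
                       lower.tail = FALSE)
    if (obs == 0) p <- 1
    return(data.frame(comparison = cmp, statistic = obs, p_value = p,
                      method = "chi_square", stringsAsFactors = FALSE))
  }
  # permutation null: shuffle surface labels over the unrolled records
  recSurface <- rep(rownames(tab), times = rowSums(tab))
  recTerm <- unlist(lapply(seq_len(nrow(tab)), function(i)
    rep(colnames(tab), times = tab[i, ])))
  set.seed(seed)
  perm <- replicate(nPermutations, {
    shuf <- sample(recSurface)
    .chisqStat(table(shuf, recTerm))
  })
  p <- (1 + sum(perm >= obs - 1e-12)) / (1 + nPermutations)
  if (obs == 0) p <- 1
  data.frame(comparison = cmp, statistic = obs, p_value = p,
             method = "permutation", stringsAsFactors = FALSE)
}

# Pearson chi-squared statistic without continuity correction
.chisqStat <- function(tab) {
  tab <- as.matrix(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ok <- expd > 0
  sum((tab[ok] - expd[ok])^2 / expd[ok])
}
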