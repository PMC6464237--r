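#' Empirical quantile of a patient-count vector
#'
#' The hotspot rule selects variants whose patient count exceeds the 95th
#' quantile of the vector of per-variant patient numbers. The default
#' estimator is linear interpolation of order statistics
#' (\code{stats::quantile} type 7, the common statistical-environment
#' default); \code{"nearest_rank"} (type 1) is available as an alternative.
#'
#' @param counts non-negative numeric vector (one entry per variant).
#' @param level quantile level in (0,1); default 0.95.
#' @param estimator \code{"linear"} (default) or \code{"nearest_rank"}.
#' @return the quantile threshold (numeric scalar).
#' @examples
#' patientCountQuantile(c(1, 1, 1, 1, 100), level = 0.5)  # 1
#' @export
patientCountQuantile <- function(counts, level = 0.95,
                                 estimator = c("linear", "nearest_rank")) {
  estimator <- match.arg(estimator)
  if (!length(counts)) .err("vhlG2P_input_error", "empty count vector")
  if (level <= 0 || level >= 1)
    .err("vhlG2P_input_error", "quantile level must be in (0,1)")
  type <- if (estimator == "linear") 7L else 1L
  unname(stats::quantile(as.numeric(counts), probs = level, type = type,
                         names = FALSE))
}

#' Detect frequently mutated positions (hotspots)
#'
#' Applies the patient-count quantile rule: variants whose \code{n_patients}
#' is (strictly, by default) greater than the empirical quantile of the
#' per-variant patient-count vector are selected, then collapsed to the
#' distinct positions they occupy. Positions are ranked by total patients
#' (descending), ties broken by ascending position.
#'
#' @param x a [MutationSet-class].
#' @param level quantile level, default 0.95.
#' @param strict logical; if TRUE (default), require count > threshold,
#'   else >=.
#' @param estimator passed to [patientCountQuantile()].
#' @param aggregateBy \code{"variant"} (default: quantile over per-variant
#'   counts) or \code{"position"} (quantile over per-position totals).
#' @return data.frame with one row per hotspot position: \code{position},
#'   \code{total_patients}, \code{n_distinct_variants}, \code{variants}
#'   (comma-separated mutant residues), plus attribute \code{"threshold"}.
#' @export
detectHotspots <- function(x, level = 0.95, strict = TRUE,
                           estimator = c("linear", "nearest_rank"),
                           aggregateBy = c("variant", "position")) {
  estimator <- match.arg(estimator)
  aggregateBy <- match.arg(aggregateBy)
  if (length(x) == 0L) .err("vhlG2P_input_error", "empty mutation set")
  v <- mutationTable(x)
  if (aggregateBy == "variant") {
    thr <- patientCountQuantile(v$n_patients, level, estimator)
    sel <- if (strict) v$n_patients > thr else v$n_patients >= thr
    v <- v[sel, , drop = FALSE]
  } else {
    tot <- tapply(v$n_patients, v$position, sum)
    thr <- patientCountQuantile(as.numeric(tot), level, estimator)
    sel <- if (strict) tot > thr else tot >= thr
    v <- v[v$position %in% as.integer(names(tot)[sel]), , drop = FALSE]
  }
  if (!nrow(v)) {
    out <- data.frame(position = integer(), total_patients = integer(),
                      n_distinct_variants = integer(), variants = character(),
                      stringsAsFactors = FALSE)
    attr(out, "threshold") <- thr
    return(out)
  }
  sp <- split(v, v$position)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(position = d$position[1],
               total_patients = sum(d$n_patients),
               n_distinct_variants = length(unique(d$mut_aa)),
               variants = paste(sort(unique(d$mut_aa)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$total_patients, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Number of distinct variants reported at a position
#'
#' Distinct amino-acid substitutions described at one residue, e.g. a
#' heavily re-mutated position like Asn78 carries several different
#' variants.
#'
#' @param x a [MutationSet-class].
#' @param position 1-based residue position.
#' @return integer; 0 when no record exists at the position.
#' @export
variantMultiplicity <- function(x, position) {
  v <- mutationTable(x)
  length(unique(v$mut_aa[v$position == position]))
}
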