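# Internal helpers shared across modules. Collated first.

# three-letter -> one-letter amino acid map (standard 20)
.AA321 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
            Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
            Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
            Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

emptyVariantFrame <- function() {
  data.frame(variant = character(), position = integer(),
             wt_aa = character(), mut_aa = character(),
             synonymous = logical(), n_patients = integer(),
             source_id = character(), stringsAsFactors = FALSE)
}

#' Controlled phenotype vocabulary
#'
#' The closed list of normalized VHL phenotype terms used throughout the
#' package. Renal manifestations (ccRCC, RCC, renal cysts) are collapsed into
#' \code{renal_disease}; unknown labels map to \code{other}.
#'
#' @return character vector of phenotype terms.
#' @export
phenotypeVocabulary <- function() {
  c("renal_disease", "pheochromocytoma", "hemangioblastoma_cerebellar",
    "hemangioblastoma_retinal", "paraganglioma", "pnet", "pancreatic_cyst",
    "polycythemia", "elst", "colorectal_cancer", "glial_tumor",
    "cystadenoma", "si_net", "other")
}

# stop with a classed condition so callers/tests can distinguish error kinds
.err <- function(class, ...) {
  stop(structure(class = c(class, "vhlG2P_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.assertFile <- function(path) {
  if (!file.exists(path)) .err("vhlG2P_input_error", "file not found: ", path)
}

# expand "54-113,157-171" (1-based, inclusive) into an integer vector
.parseRanges <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(integer())
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  out <- lapply(trimws(parts), function(p) {
    m <- regmatches(p, regexec("^([0-9]+)(?:-([0-9]+))?$", p))[[1]]
    if (!length(m)) .err("vhlG2P_parse_error", "bad range token: ", p)
    a <- as.integer(m[2])
    b <- if (nzchar(m[3])) as.integer(m[3]) else a
    if (b < a) .err("vhlG2P_parse_error", "descending range: ", p)
    a:b
  })
  sort(unique(unlist(out)))
}

.collapseRanges <- function(res) {
  res <- sort(unique(as.integer(res)))
  if (!length(res)) return("")
  brk <- c(0L, which(diff(res) != 1L), length(res))
  paste(vapply(seq_len(length(brk) - 1L), function(i) {
    a <- res[brk[i] + 1L]; b <- res[brk[i + 1L]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, character(1)), collapse = ",")
}
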