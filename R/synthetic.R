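# Synthetic-data module: generators for every input the pipeline consumes,
# with ground-truth sidecars, so each analysis stage is testable offline.

#' Synthetic-data generator configuration
#'
#' Assembles (and defaults) the knobs of [generateMutationTable()]. Patient
#' counts follow a geometric distribution (most variants are rare, few are
#' frequent, matching the heavy-tailed structure of patient-ranked curated
#' tables); hotspot positions get their counts scaled by planted
#' multipliers; phenotypes are sampled from base rates with
#' surface-conditional odds multipliers; a configurable fraction of
#' variants carries a single phenotype (default 0.45, echoing the roughly
#' 742/1,670 single-phenotype share of curated VHL records).
#'
#' @param n_variants number of variant rows to draw.
#' @param protein_length protein length (default 213, pVHL30).
#' @param hotspots named numeric vector: position -> patient-count
#'   multiplier (> 0).
#' @param base_rates named probabilities over [phenotypeVocabulary()] terms
#'   (need not sum to 1; used as sampling weights).
#' @param enrichments data.frame with columns \code{surface_id},
#'   \code{term}, \code{odds}: odds multipliers applied to a term when the
#'   variant position lies on the surface.
#' @param single_fraction fraction of variants with a single phenotype.
#' @param geom_prob success probability of the geometric patient-count draw.
#' @param seed integer RNG seed.
#' @param surfaces a [SurfaceSet-class] used to resolve enrichments.
#' @return list of class \code{vhlSynthConfig}.
#' @export
synthConfig <- function(n_variants = 500L, protein_length = 213L,
                        hotspots = numeric(),
                        base_rates = defaultBaseRates(),
                        enrichments = NULL, single_fraction = 0.45,
                        geom_prob = 0.6, seed = 1L,
                        surfaces = defaultSurfaces()) {
  if (any(hotspots <= 0)) .err("vhlG2P_config_error", "multipliers must be > 0")
  if (any(base_rates < 0 | base_rates > 1))
    .err("vhlG2P_config_error", "base rates must be probabilities")
  if (length(hotspots) &&
      any(as.integer(names(hotspots)) > protein_length))
    .err("vhlG2P_config_error", "hotspot position outside the protein")
  if (max(unlist(surfaces@surfaces)) > protein_length)
    .err("vhlG2P_config_error", "protein_length below max surface residue")
  structure(list(n_variants = as.integer(n_variants),
                 protein_length = as.integer(protein_length),
                 hotspots = hotspots, base_rates = base_rates,
                 enrichments = enrichments,
                 single_fraction = single_fraction, geom_prob = geom_prob,
                 seed = as.integer(seed), surfaces = surfaces),
            class = "vhlSynthConfig")
}

#' Default phenotype base rates for the generator
#'
#' Roughly mirrors the qualitative ordering of single-phenotype VHL
#' manifestations (renal disease dominant, then pheochromocytoma and the
#' hemangioblastomas, with a tail of rare manifestations).
#'
#' @return named numeric vector of sampling weights.
#' @export
defaultBaseRates <- function() {
  c(renal_disease = 0.45, pheochromocytoma = 0.17,
    hemangioblastoma_cerebellar = 0.12, hemangioblastoma_retinal = 0.08,
    pnet = 0.05, pancreatic_cyst = 0.05, polycythemia = 0.03,
    colorectal_cancer = 0.02, glial_tumor = 0.01, cystadenoma = 0.01,
    si_net = 0.005, paraganglioma = 0.005, elst = 0.005)
}

# raw-label spellings per term, to exercise normalization
.RAW_LABELS <- list(
  renal_disease = c("ccRCC", "RCC", "renal cysts", "renal carcinoma"),
  pheochromocytoma = c("pheochromocytoma", "Pheochromocytoma"),
  hemangioblastoma_cerebellar = c("cerebellar hemangioblastoma",
                                  "CNS hemangioblastoma"),
  hemangioblastoma_retinal = c("retinal hemangioblastoma",
                               "retinal angioma"))

.rawLabelFor <- function(term, k) {
  alts <- .RAW_LABELS[[term]]
  if (is.null(alts)) term else alts[(k %% length(alts)) + 1L]
}

#' Generate a synthetic curated mutation table
#'
#' Draws variant positions uniformly over the protein except planted
#' hotspot positions (each guaranteed at least one variant, patient counts
#' scaled by the planted multiplier), samples phenotype sets from base
#' rates with surface-conditional odds multipliers, and emits raw synonym
#' spellings so phenotype normalization has real work to do. A pure
#' function of the config (including its seed).
#'
#' @param config a [synthConfig()] list.
#' @param path optional TSV output path; a ground-truth sidecar
#'   (\code{<path>.truth.json}) is written alongside.
#' @return a [MutationSet-class] with attribute \code{"truth"}: list with
#'   the planted hotspot set, multipliers, enrichment map, seed and the
#'   exact number of single-phenotype rows.
#' @export
generateMutationTable <- function(config, path = NULL) {
  stopifnot(inherits(config, "vhlSynthConfig"))
  set.seed(config$seed)
  n <- config$n_variants
  L <- config$protein_length
  hotPos <- as.integer(names(config$hotspots))
  pos <- sample.int(L, n, replace = TRUE)
  if (length(hotPos)) pos[seq_along(hotPos)] <- hotPos
  counts <- stats::rgeom(n, config$geom_prob) + 1L
  if (length(hotPos)) {
    for (i in seq_along(hotPos)) {
      at <- which(pos == hotPos[i])
      counts[at] <- as.integer(ceiling(counts[at] * config$hotspots[i]))
    }
  }
  aa <- names(.AA321)
  wt3 <- aa[sample.int(20L, n, replace = TRUE)]
  mshift <- sample.int(19L, n, replace = TRUE)
  mut3 <- aa[((match(wt3, aa) - 1L + mshift) %% 20L) + 1L]
  variant <- paste0("p.", wt3, pos, mut3)

  terms <- names(config$base_rates)
  # per-variant term weights, with surface-conditional odds multipliers
  weights <- matrix(rep(config$base_rates, each = n), nrow = n,
                    dimnames = list(NULL, terms))
  if (!is.null(config$enrichments) && nrow(config$enrichments)) {
    for (k in seq_len(nrow(config$enrichments))) {
      e <- config$enrichments[k, ]
      res <- surfaceResidues(config$surfaces, e$surface_id)
      on <- pos %in% res
      p <- weights[on, e$term]
      o <- p / (1 - p) * e$odds
      weights[on, e$term] <- o / (1 + o)
    }
  }
  single <- stats::runif(n) < config$single_fraction
  phen <- vector("list", n)
  raw <- character(n)
  for (i in seq_len(n)) {
    size <- if (single[i]) 1L else 2L + (stats::runif(1) < 0.3)
    tt <- sample(terms, size, prob = weights[i, ])
    phen[[i]] <- sort(tt)
    raw[i] <- paste(vapply(seq_along(tt), function(j)
      .rawLabelFor(tt[j], i + j), character(1)), collapse = ";")
  }
  ms <- MutationSet(variant = variant, position = pos,
                    wt_aa = unname(.AA321[wt3]), mut_aa = unname(.AA321[mut3]),
                    n_patients = counts, phenotypes = phen,
                    source_id = sprintf("synth:%d", seq_len(n)))
  truth <- list(seed = config$seed,
                hotspot_positions = hotPos,
                multipliers = unname(config$hotspots),
                enrichments = config$enrichments,
                n_single = sum(single))
  attr(ms, "truth") <- truth
  if (!is.null(path)) {
    tab <- data.frame(variant = variant, n_patients = counts,
                      phenotypes = raw,
                      source = sprintf("synth:%d", seq_len(n)),
                      stringsAsFactors = FALSE)
    hdr <- paste0("# vhlG2P synthetic mutation table; seed=", config$seed,
                  "; n=", n)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(tab, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, null = "null")
  }
  ms
}

#' Generate a toy structure with known contact truth
#'
#' Three ideal-geometry cases for validating contact typing:
#' \describe{
#'   \item{helix}{a 12-residue poly-alanine helix: backbone/CB packing only,
#'     so no salt bridges and no pi-pi edges.}
#'   \item{argglu}{an Arg and a Glu residue with the NH1-OE1 guanidinium/
#'     carboxylate gap set to \code{distance}: a salt bridge iff
#'     \code{distance} is within the salt-bridge cutoff; all other atom
#'     pairs are farther apart.}
#'   \item{phephe}{two stacked Phe rings with centroids \code{distance}
#'     apart: a pi-pi edge iff within the centroid cutoff.}
#' }
#'
#' @param case one of \code{"helix"}, \code{"argglu"}, \code{"phephe"}.
#' @param distance the constructed gap in Angstrom (ignored for
#'   \code{helix}).
#' @param path optional PDB output path.
#' @return a [ProteinStructure-class] with attribute \code{"truth"}: the
#'   intended contact list (possibly empty).
#' @export
generateToyStructure <- function(case = c("helix", "argglu", "phephe"),
                                 distance = 3.0, path = NULL) {
  case <- match.arg(case)
  if (distance <= 0) .err("vhlG2P_config_error", "distance must be > 0")
  atoms <- switch(case,
    helix = .toyHelix(12L),
    argglu = .toyArgGlu(distance),
    phephe = .toyPhePhe(distance))
  p <- contactParams()
  truth <- switch(case,
    helix = data.frame(residue_i = integer(), residue_j = integer(),
                       contact_type = character(), stringsAsFactors = FALSE),
    argglu = if (distance <= p$salt_bridge)
      data.frame(residue_i = 10L, residue_j = 20L,
                 contact_type = "salt_bridge", stringsAsFactors = FALSE)
    else data.frame(residue_i = integer(), residue_j = integer(),
                    contact_type = character(), stringsAsFactors = FALSE),
    phephe = if (distance <= p$pipi)
      data.frame(residue_i = 10L, residue_j = 20L,
                 contact_type = "pipi", stringsAsFactors = FALSE)
    else data.frame(residue_i = integer(), residue_j = integer(),
                    contact_type = character(), stringsAsFactors = FALSE))
  if (!is.null(path)) .writePDB(atoms, path)
  st <- ProteinStructure(atoms)
  attr(st, "truth") <- truth
  st
}

.atomRow <- function(resno, resid, elety, x, y, z, chain = "A") {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             element = substr(elety, 1, 1), x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# parametric alpha-helix approximation: CA on a 2.3 A radius, 1.5 A rise,
# 100 degrees per residue; N/C on the same curve at +-0.35 residue offsets,
# O radially out from C, CB radially out from CA.
.toyHelix <- function(n) {
  coord <- function(t, radius = 2.3) {
    ang <- t * 100 * pi / 180
    c(radius * cos(ang), radius * sin(ang), 1.5 * t)
  }
  rows <- list()
  for (i in seq_len(n)) {
    ca <- coord(i)
    nn <- coord(i - 0.35, 1.9)
    cc <- coord(i + 0.35, 1.9)
    oo <- coord(i + 0.35, 3.1)
    ang <- i * 100 * pi / 180
    cb <- c(3.8 * cos(ang), 3.8 * sin(ang), 1.5 * i)
    rows[[i]] <- rbind(
      .atomRow(i, "ALA", "N", nn[1], nn[2], nn[3]),
      .atomRow(i, "ALA", "CA", ca[1], ca[2], ca[3]),
      .atomRow(i, "ALA", "C", cc[1], cc[2], cc[3]),
      .atomRow(i, "ALA", "O", oo[1], oo[2], oo[3]),
      .atomRow(i, "ALA", "CB", cb[1], cb[2], cb[3]))
  }
  do.call(rbind, rows)
}

# Arg (resno 10) extended along +x, Glu (resno 20) approaching from the
# right; the NH1..OE1 gap is exactly `d` and is the closest inter-residue
# atom pair by construction.
.toyArgGlu <- function(d) {
  arg <- rbind(
    .atomRow(10L, "ARG", "N", -1.2, 1.0, 0),
    .atomRow(10L, "ARG", "CA", 0, 0, 0),
    .atomRow(10L, "ARG", "C", -0.5, -1.4, 0),
    .atomRow(10L, "ARG", "O", -1.7, -1.6, 0),
    .atomRow(10L, "ARG", "CB", 1.5, 0, 0),
    .atomRow(10L, "ARG", "CG", 3.0, 0, 0),
    .atomRow(10L, "ARG", "CD", 4.5, 0, 0),
    .atomRow(10L, "ARG", "NE", 6.0, 0, 0),
    .atomRow(10L, "ARG", "CZ", 7.5, 0, 0),
    .atomRow(10L, "ARG", "NH1", 9.0, 0, 0),
    .atomRow(10L, "ARG", "NH2", 7.9, 1.3, 0))
  x0 <- 9.0 + d
  glu <- rbind(
    .atomRow(20L, "GLU", "OE1", x0, 0, 0),
    .atomRow(20L, "GLU", "OE2", x0 + 0.7, -1.1, 0),
    .atomRow(20L, "GLU", "CD", x0 + 1.25, 0, 0),
    .atomRow(20L, "GLU", "CG", x0 + 2.75, 0, 0),
    .atomRow(20L, "GLU", "CB", x0 + 4.25, 0, 0),
    .atomRow(20L, "GLU", "CA", x0 + 5.75, 0, 0),
    .atomRow(20L, "GLU", "N", x0 + 6.3, 1.3, 0),
    .atomRow(20L, "GLU", "C", x0 + 6.5, -1.3, 0),
    .atomRow(20L, "GLU", "O", x0 + 7.7, -1.5, 0))
  rbind(arg, glu)
}

# two Phe rings stacked face-to-face along z, centroids `d` apart
.toyPhePhe <- function(d) {
  hex <- function(resno, z) {
    ang <- (0:5) * 60 * pi / 180
    name <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    ring <- do.call(rbind, lapply(1:6, function(k)
      .atomRow(resno, "PHE", name[k], 1.39 * cos(ang[k]),
               1.39 * sin(ang[k]), z)))
    rbind(ring,
          .atomRow(resno, "PHE", "CB", 2.9, 0, z),
          .atomRow(resno, "PHE", "CA", 4.4, 0, z),
          .atomRow(resno, "PHE", "N", 5.0, 1.3, z),
          .atomRow(resno, "PHE", "C", 5.2, -1.3, z),
          .atomRow(resno, "PHE", "O", 6.4, -1.5, z))
  }
  rbind(hex(10L, 0), hex(20L, d))
}

#' Miniature hypoxia-response Petri net fixture
#'
#' A 9-place / 8-transition qualitative distillation of the pVHL hypoxia
#' pathway: a HIF-1a synthesis source; a pVHL-dependent HIF degradation
#' transition (the only HIF sink); HIF-driven VEGF production; an AKT
#' branch with a constitutive activation source, pVHL-dependent
#' inhibition, and downstream survival-signaling and glycolysis outputs;
#' and a MAPK place draining into POMC. Place and transition ids reuse the
#' pathway-model aliases \code{p_54} (MAPK activation), \code{p_38}
#' (AKT-1), \code{p_39} (survival signaling), \code{p_60} (glycolysis),
#' \code{t_181} (HIF degradation branch) and \code{t_109} (GSK3B
#' glycogen/glycolysis branch), so perturbation recipes written against
#' those ids run end-to-end on the fixture.
#'
#' @param path optional JSON output path.
#' @return the net spec as a list (pass to [buildNet()]).
#' @export
fixturePetriNet <- function(path = NULL) {
  spec <- list(
    places = data.frame(
      id = c("HIF", "HIF_degraded", "VEGF", "pVHL", "p_54", "p_38",
             "p_39", "p_60", "POMC"),
      label = c("HIF-1a", "degraded HIF-1a", "VEGF production",
                "pVHL (VCB complex)", "MAPK activation", "AKT-1 active",
                "survival signaling", "glycolysis", "POMC"),
      initial = c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
      stringsAsFactors = FALSE),
    transitions = data.frame(
      id = c("t_hif_synthesis", "t_181", "t_vegf_production",
             "t_akt_activation", "t_akt_inhibition", "t_survival",
             "t_109", "t_pomc_synthesis"),
      label = c("HIF-1a synthesis", "pVHL-dependent HIF degradation",
                "HIF-driven VEGF production", "AKT-1 activation",
                "pVHL-dependent AKT-1 inhibition",
                "AKT-driven survival signaling",
                "GSK3B branch: AKT-driven glycolysis",
                "MAPK-driven POMC synthesis"),
      stringsAsFactors = FALSE),
    arcs = data.frame(
      from = c("t_hif_synthesis",
               "HIF", "pVHL", "t_181",
               "HIF", "t_vegf_production", "t_vegf_production",
               "t_akt_activation",
               "p_38", "pVHL", "t_akt_inhibition",
               "p_38", "t_survival", "t_survival",
               "p_38", "t_109", "t_109",
               "p_54", "t_pomc_synthesis"),
      to = c("HIF",
             "t_181", "t_181", "pVHL",
             "t_vegf_production", "HIF", "VEGF",
             "p_38",
             "t_akt_inhibition", "t_akt_inhibition", "pVHL",
             "t_survival", "p_38", "p_39",
             "t_109", "p_38", "p_60",
             "t_pomc_synthesis", "POMC"),
      weight = 1L, stringsAsFactors = FALSE))
  spec$arcs <- rbind(spec$arcs,
                     data.frame(from = "t_181", to = "HIF_degraded",
                                weight = 1L, stringsAsFactors = FALSE))
  if (!is.null(path))
    jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows")
  spec
}

#' Deterministic synthetic curated mutation table
#'
#' A fully deterministic, code-built emulation of a curated pVHL variant
#' table at the scale of published curations (385 variant records).
#' It encodes, by construction: 18 high-patient-count positions that the
#' strict 95th-quantile rule selects, with Arg167 top-ranked at 366
#' patients over its two main variants (p.Arg167Trp, p.Arg167Gln); seven
#' distinct substitutions at Asn78; single-phenotype variant subsets whose
#' positional footprints drive the conserved-interactor snapshot rows when
#' paired with [syntheticInteractors()]; and missense overlap of exactly
#' the 14 mutated PTM sites of [syntheticPTMSites()]. SYNTHETIC: the
#' phenotype assignments and filler variants are constructed, not curated
#' from the literature.
#'
#' @return a [MutationSet-class] with 385 variant records.
#' @export
syntheticCuratedTable <- function() {
  rd <- "renal_disease"; ph <- "pheochromocytoma"
  hc <- "hemangioblastoma_cerebellar"; hr <- "hemangioblastoma_retinal"
  multi1 <- list(c(rd, ph, hc)); multi2 <- list(c(rd, hr))
  multi3 <- list(c(rd, ph, "paraganglioma"))
  multi4 <- list(c(rd, hc, "pancreatic_cyst"))
  multi5 <- list(c(rd, "cystadenoma"))
  row <- function(pos, wt, mut, n, phen) {
    inv <- stats::setNames(names(.AA321), .AA321)
    data.frame(variant = paste0("p.", inv[wt], pos, inv[mut]),
               position = pos, wt_aa = wt, mut_aa = mut,
               n_patients = n, stringsAsFactors = FALSE)
  }
  specs <- list(
    # 18 frequently mutated positions (19 variants above the quantile rule)
    list(167, "R", "W", 200, multi1), list(167, "R", "Q", 166, multi3),
    list(78, "N", "S", 150, multi1), list(98, "Y", "H", 140, multi2),
    list(65, "S", "L", 130, multi1), list(161, "R", "Q", 120, multi3),
    list(81, "P", "S", 110, multi4), list(86, "P", "L", 100, multi1),
    list(117, "W", "G", 90, multi5), list(111, "S", "N", 80, multi2),
    list(121, "G", "D", 70, multi1), list(149, "A", "S", 60, multi4),
    list(158, "E", "K", 50, multi1), list(162, "C", "F", 40, multi2),
    list(164, "Q", "H", 30, multi3), list(166, "V", "F", 20, multi1),
    list(176, "L", "P", 15, multi2), list(178, "D", "G", 12, multi1),
    list(200, "R", "W", 10, list(c("polycythemia", rd))),
    # six further substitutions at Asn78 (multiplicity 7 in total)
    list(78, "N", "T", 1, multi2), list(78, "N", "K", 1, multi1),
    list(78, "N", "I", 1, multi4), list(78, "N", "H", 2, multi2),
    list(78, "N", "Y", 1, multi1), list(78, "N", "D", 1, multi2),
    # pheochromocytoma-only singles
    list(33, "S", "A", 2, list(ph)), list(65, "S", "W", 1, list(ph)),
    list(81, "P", "L", 1, list(ph)), list(158, "E", "Q", 1, list(ph)),
    list(188, "Q", "K", 1, list(ph)),
    # hemangioblastoma-only singles (cerebellar / retinal)
    list(90, "C", "Y", 1, list(hc)), list(98, "Y", "C", 2, list(hc)),
    list(117, "W", "R", 1, list(hr)), list(90, "C", "S", 1, list(hr)),
    # renal-only singles (footprint covers every interactor interface)
    list(44, "V", "M", 3, list(rd)), list(65, "S", "P", 1, list(rd)),
    list(80, "P", "T", 1, list(rd)),
    list(98, "Y", "N", 1, list(rd)), list(111, "S", "C", 2, list(rd)),
    list(117, "W", "C", 1, list(rd)), list(121, "G", "R", 1, list(rd)),
    list(158, "E", "G", 1, list(rd)), list(164, "Q", "R", 1, list(rd)),
    list(167, "R", "L", 1, list(rd)), list(200, "R", "Q", 1, list(rd)),
    list(38, "S", "F", 1, list(rd)), list(171, "K", "N", 1, list(rd)),
    # PTM-site overlaps named in the curation narrative
    list(68, "S", "W", 2, list(c(rd, hr, ph))),
    list(72, "S", "P", 1, list(c(hc, rd))),
    list(79, "R", "C", 1, list(c(rd, "polycythemia"))),
    list(82, "R", "L", 1, list("pnet")),
    list(159, "K", "E", 1, list(c(rd, ph))),
    # NEK1-site overlaps (synthetic positions)
    list(75, "T", "M", 1, multi1), list(89, "S", "L", 1, multi2),
    list(101, "S", "R", 1, multi1), list(112, "T", "I", 1, multi4),
    list(122, "S", "G", 1, multi2),
    # other single phenotypes
    list(204, "P", "S", 1, list("colorectal_cancer")),
    list(200, "R", "G", 1, list("colorectal_cancer")),
    list(56, "E", "K", 1, list("pancreatic_cyst")),
    list(72, "S", "C", 1, list("pnet")),
    list(175, "Y", "C", 1, list("polycythemia")),
    list(104, "G", "V", 1, list("glial_tumor")))
  named <- do.call(rbind, lapply(specs, function(s)
    row(s[[1]], s[[2]], s[[3]], s[[4]], NULL)))
  phen <- lapply(specs, function(s) {
    p <- s[[5]]
    sort(unique(if (is.list(p)) p[[1]] else p))
  })
  # deterministic fillers, patient counts in {1,2,3}; the low-count block is
  # sized (385 variants total) so the 95th-quantile threshold of the count
  # vector interpolates inside the low block and equals 3, cleanly below
  # the 19 high-count variants; positions avoid the unmutated PTM sites
  # (43, 134, 146, 155, 196) and position 78, whose variant multiplicity
  # is fixed at seven by the named rows
  nFill <- 385L - nrow(named)
  avoid <- c(43L, 78L, 134L, 146L, 155L, 196L)
  candidates <- setdiff(seq_len(213L), avoid)
  fpos <- candidates[((seq_len(nFill) * 7L) %% length(candidates)) + 1L]
  aa <- unname(.AA321)
  fwt <- aa[(fpos %% 20L) + 1L]
  fmut <- aa[((fpos + 3L + seq_len(nFill)) %% 20L) + 1L]
  same <- fwt == fmut
  fmut[same] <- aa[((match(fmut[same], aa)) %% 20L) + 1L]
  fcount <- rep_len(c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 3L, 1L, 2L), nFill)
  inv <- stats::setNames(names(.AA321), .AA321)
  fill <- data.frame(variant = paste0("p.", inv[fwt], fpos, inv[fmut]),
                     position = fpos, wt_aa = fwt, mut_aa = fmut,
                     n_patients = fcount, stringsAsFactors = FALSE)
  fillPhen <- rep(list(c(rd, ph)), nFill)
  fillPhen[seq(1, nFill, by = 3)] <- list(c(rd, hc, hr))
  fillPhen[seq(2, nFill, by = 5)] <- list(c(ph, "paraganglioma"))
  all <- rbind(named, fill)
  MutationSet(variant = all$variant, position = all$position,
              wt_aa = all$wt_aa, mut_aa = all$mut_aa,
              n_patients = all$n_patients,
              phenotypes = c(phen, fillPhen),
              source_id = rep("synthetic-curation", nrow(all)))
}

#' Packaged synthetic interactor table
#'
#' Loads the packaged SYNTHETIC interactor table (gene symbol, accession,
#' binding-interface residue ranges) emulating a high-confidence curated
#' interactor list. Binding ranges are constructed so that, against
#' [syntheticCuratedTable()], the conserved-interactor snapshot reproduces
#' the published qualitative rows (pheochromocytoma retains HSPA4 and
#' AKT1; hemangioblastoma retains TP53, ID2, ELAVL1, E2F1, ELOC).
#'
#' @return data.frame as from [readInteractorTable()].
#' @export
syntheticInteractors <- function() {
  readInteractorTable(system.file("extdata", "vhl_interactors_synthetic.tsv",
                                  package = "vhlG2P"))
}

#' Packaged synthetic PTM-site table
#'
#' Loads the packaged SYNTHETIC PTM-site table emulating the curated pVHL
#' PTM catalogue: phosphorylation sites for CSNK2A1 (Ser33/38/43), GSK3B
#' (Ser68), AURKA/CSNK1A1 (Ser72), CHEK2 (Ser111) and seven NEK1 sites,
#' plus neddylation (Lys159), sumoylation/ubiquitination (Lys171, Lys155,
#' Lys196) and methylation (Arg79, Arg82). Exactly 14 of these sites are
#' overlapped by missense variants of [syntheticCuratedTable()]. NEK1 site
#' positions are synthetic placements on surfaces B/C.
#'
#' @return data.frame as from [readPTMTable()].
#' @export
syntheticPTMSites <- function() {
  readPTMTable(system.file("extdata", "vhl_ptm_sites_synthetic.tsv",
                           package = "vhlG2P"))
}
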