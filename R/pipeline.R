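#' Run the full genotype-phenotype analysis pipeline
#'
#' Orchestrates the stages (parse, hotspots, surfaces, residue network,
#' impairment, Petri simulation) over a config, writing per-stage TSV/JSON
#' outputs plus a manifest with the package version, parameters, seed and
#' input checksums. Stage toggles allow partial runs; with all stages off
#' only the manifest is written. Deterministic given (inputs, config,
#' seed); existing outputs are only overwritten with \code{force = TRUE}.
#'
#' @param config list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{inputs}{named paths: \code{mutations}, and optionally
#'       \code{interactors}, \code{ptm}, \code{surfaces}, \code{structure},
#'       \code{net}.}
#'     \item{stages}{named logical toggles: \code{hotspots},
#'       \code{surfaces}, \code{network}, \code{impairment}, \code{petri}
#'       (default all TRUE; \code{parse} always runs when any stage needs
#'       it).}
#'     \item{params}{optional per-stage parameter lists, e.g.
#'       \code{hotspots = list(level = 0.95, strict = TRUE)},
#'       \code{petri = list(steps = 2000, replicates = 20, knockout =
#'       "t_181")}.}
#'     \item{seed}{integer seed recorded and used by stochastic stages.}
#'   }
#' @param outdir output directory (created if missing).
#' @param force overwrite existing outputs.
#' @return invisibly, the manifest list (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config, outdir, force = FALSE) {
  if (is.character(config)) {
    .assertFile(config)
    config <- yaml::read_yaml(config)
  }
  stages <- utils::modifyList(
    list(hotspots = TRUE, surfaces = TRUE, network = TRUE,
         impairment = TRUE, petri = TRUE),
    if (is.null(config$stages)) list() else config$stages)
  params <- if (is.null(config$params)) list() else config$params
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  inputs <- config$inputs
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  outfile <- function(name) {
    f <- file.path(outdir, name)
    if (file.exists(f) && !force)
      .err("vhlG2P_output_error", "output exists (use force = TRUE): ", f)
    f
  }
  manifest <- list(package = "vhlG2P",
                   version = as.character(utils::packageVersion("vhlG2P")),
                   seed = seed, stages_completed = character(),
                   inputs = lapply(inputs, function(p)
                     list(path = p, md5 = unname(tools::md5sum(p)))),
                   params = params)
  completed <- character()
  fail <- function(stage, e)
    .err("vhlG2P_stage_error", "stage '", stage, "' failed: ",
         conditionMessage(e))

  needParse <- any(unlist(stages[c("hotspots", "surfaces", "impairment")]))
  ms <- NULL
  if (needParse) {
    tryCatch({
      ms <- readMutationTable(inputs$mutations)
      completed <- c(completed, "parse")
    }, error = function(e) fail("parse", e))
  }
  surfaces <- if (!is.null(inputs$surfaces))
    readSurfaceConfig(inputs$surfaces) else defaultSurfaces()

  if (isTRUE(stages$hotspots)) tryCatch({
    p <- utils::modifyList(list(level = 0.95, strict = TRUE),
                           if (is.null(params$hotspots)) list() else params$hotspots)
    hs <- detectHotspots(ms, level = p$level, strict = p$strict)
    utils::write.table(hs, outfile("hotspots.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    completed <- c(completed, "hotspots")
  }, error = function(e) fail("hotspots", e))

  if (isTRUE(stages$surfaces)) tryCatch({
    single <- filterSinglePhenotype(dropSynonymous(ms))
    stats <- surfaceMutationStats(dropSynonymous(ms), surfaces)
    utils::write.table(stats, outfile("surface_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dists <- lapply(c(surfaceIDs(surfaces), "overall"), function(id)
      phenotypeDistribution(single, surfaces, id))
    json <- lapply(dists, function(d)
      list(surface = d@surfaceId, n_records = d@nRecords,
           proportions = as.list(phenotypeProportions(d))))
    jsonlite::write_json(json, outfile("phenotype_distributions.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    completed <- c(completed, "surfaces")
  }, error = function(e) fail("surfaces", e))

  if (isTRUE(stages$network) && !is.null(inputs$structure)) tryCatch({
    st <- readStructure(inputs$structure,
                        chain = if (is.null(params$network$chain)) NULL
                                else params$network$chain)
    net <- detectContacts(st)
    writeEdgeList(net, outfile("contacts.tsv"))
    completed <- c(completed, "network")
  }, error = function(e) fail("network", e))

  if (isTRUE(stages$impairment) && !is.null(inputs$interactors)) tryCatch({
    interactors <- readInteractorTable(inputs$interactors)
    im <- buildImpairmentMatrix(ms, interactors)
    writeImpairmentMatrix(im, outfile("impairment_matrix.tsv"))
    if (!is.null(inputs$ptm)) {
      ov <- ptmOverlap(ms, readPTMTable(inputs$ptm))
      utils::write.table(ov, outfile("ptm_overlap.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    completed <- c(completed, "impairment")
  }, error = function(e) fail("impairment", e))

  if (isTRUE(stages$petri) && !is.null(inputs$net)) tryCatch({
    p <- utils::modifyList(list(steps = 2000L, replicates = 20L,
                                knockout = NULL, bump = NULL),
                           if (is.null(params$petri)) list() else params$petri)
    net <- buildNet(inputs$net)
    wt <- simulateNet(net, steps = p$steps, replicates = p$replicates,
                      seed = seed)
    res <- list(wild_type = experimentSummary(wt))
    if (!is.null(p$knockout) || !is.null(p$bump)) {
      pnet <- if (!is.null(p$knockout)) knockout(net, p$knockout) else net
      m0 <- initialMarking(net)
      if (!is.null(p$bump)) m0 <- perturbMarking(m0, unlist(p$bump))
      pe <- simulateNet(pnet, initial = m0, steps = p$steps,
                        replicates = p$replicates, seed = seed)
      res$perturbed <- experimentSummary(pe)
      res$comparison <- compareExperiments(wt, pe)
    }
    jsonlite::write_json(res, outfile("petri_results.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    completed <- c(completed, "petri")
  }, error = function(e) fail("petri", e))

  manifest$stages_completed <- completed
  outs <- setdiff(list.files(outdir, full.names = TRUE), file.path(outdir, "manifest.json"))
  manifest$outputs <- lapply(stats::setNames(outs, basename(outs)),
                             function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
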