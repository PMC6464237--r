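#' Build a Petri net from a spec
#'
#' The spec is a JSON file (or an equivalent R list) with fields
#' \code{places} (id, label, initial), \code{transitions} (id, label) and
#' \code{arcs} (from, to, weight). Arcs must be bipartite (place to
#' transition or vice versa) with integer weights >= 1; violations raise a
#' validation error listing the offenders.
#'
#' @param spec path to a JSON net spec, or a list with the same shape.
#' @return a [PetriNet-class].
#' @export
buildNet <- function(spec) {
  if (is.character(spec)) {
    .assertFile(spec)
    spec <- jsonlite::read_json(spec, simplifyVector = TRUE)
  }
  asdf <- function(x, cols, defaults) {
    if (is.null(x)) x <- list()
    d <- as.data.frame(x, stringsAsFactors = FALSE)
    for (cc in cols) if (!cc %in% names(d)) d[[cc]] <- defaults[[cc]]
    d[, cols, drop = FALSE]
  }
  places <- asdf(spec$places, c("id", "label", "initial"),
                 list(id = character(), label = NA_character_, initial = 0L))
  places$initial <- as.integer(places$initial)
  transitions <- asdf(spec$transitions, c("id", "label"),
                      list(id = character(), label = NA_character_))
  arcs <- asdf(spec$arcs, c("from", "to", "weight"),
               list(from = character(), to = character(), weight = 1L))
  arcs$weight <- as.integer(ifelse(is.na(arcs$weight), 1L, arcs$weight))
  net <- try(new("PetriNet", places = places, transitions = transitions,
                 arcs = arcs, disabled = character()), silent = TRUE)
  if (inherits(net, "try-error"))
    .err("vhlG2P_validation_error", attr(net, "condition")$message)
  net
}

#' Read a minimal PNML net description
#'
#' Supports the place/transition/arc subset of PNML with
#' \code{initialMarking} and \code{inscription} text elements.
#'
#' @param path PNML (XML) file.
#' @return a [PetriNet-class].
#' @export
readPNML <- function(path) {
  .assertFile(path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  num <- function(node, xp, default) {
    v <- xml2::xml_text(xml2::xml_find_first(node, xp))
    if (is.na(v) || !nzchar(v)) default else as.integer(v)
  }
  txt <- function(node, xp) {
    v <- xml2::xml_text(xml2::xml_find_first(node, xp))
    if (is.na(v)) NA_character_ else v
  }
  pl <- xml2::xml_find_all(doc, ".//place")
  tr <- xml2::xml_find_all(doc, ".//transition")
  ar <- xml2::xml_find_all(doc, ".//arc")
  buildNet(list(
    places = data.frame(
      id = xml2::xml_attr(pl, "id"),
      label = vapply(pl, txt, character(1), ".//name/text"),
      initial = vapply(pl, num, integer(1), ".//initialMarking/text", 0L),
      stringsAsFactors = FALSE),
    transitions = data.frame(
      id = xml2::xml_attr(tr, "id"),
      label = vapply(tr, txt, character(1), ".//name/text"),
      stringsAsFactors = FALSE),
    arcs = data.frame(
      from = xml2::xml_attr(ar, "source"),
      to = xml2::xml_attr(ar, "target"),
      weight = vapply(ar, num, integer(1), ".//inscription/text", 1L),
      stringsAsFactors = FALSE)))
}

#' Write a Petri net spec as JSON
#' @param net a [PetriNet-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNet <- function(net, path) {
  jsonlite::write_json(list(places = net@places,
                            transitions = net@transitions,
                            arcs = net@arcs),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Initial marking of a net
#' @param net a [PetriNet-class].
#' @return named integer vector (tokens per place).
#' @export
initialMarking <- function(net) {
  stats::setNames(as.integer(net@places$initial), net@places$id)
}

# internal compiled form: per-transition input/output place indices + weights
.compileNet <- function(net) {
  pid <- net@places$id; tid <- net@transitions$id
  a <- net@arcs
  ins <- lapply(tid, function(t) {
    sub <- a[a$to == t, , drop = FALSE]
    list(idx = match(sub$from, pid), w = sub$weight)
  })
  outs <- lapply(tid, function(t) {
    sub <- a[a$from == t, , drop = FALSE]
    list(idx = match(sub$to, pid), w = sub$weight)
  })
  list(pid = pid, tid = tid, ins = ins, outs = outs,
       enabledMask = !(tid %in% net@disabled))
}

#' Enabled transitions under a marking
#'
#' A transition is enabled when it is not knocked out and every input place
#' holds at least the arc-weight tokens. Source transitions (no input arcs)
#' are always enabled.
#'
#' @param net a [PetriNet-class].
#' @param marking named integer vector over the net's places; default the
#'   initial marking.
#' @return character vector of enabled transition ids.
#' @export
enabledTransitions <- function(net, marking = initialMarking(net)) {
  cn <- .compileNet(net)
  m <- marking[cn$pid]
  en <- vapply(seq_along(cn$tid), function(k) {
    cn$enabledMask[k] && all(m[cn$ins[[k]]$idx] >= cn$ins[[k]]$w)
  }, logical(1))
  cn$tid[en]
}

#' Fire one transition
#'
#' Consumes tokens along input arcs and produces along output arcs. Firing
#' a disabled or non-enabled transition is a state error.
#'
#' @param net a [PetriNet-class].
#' @param marking named integer vector.
#' @param transition transition id.
#' @return the successor marking (named integer vector).
#' @export
fireTransition <- function(net, marking, transition) {
  cn <- .compileNet(net)
  k <- match(transition, cn$tid)
  if (is.na(k)) .err("vhlG2P_input_error", "unknown transition: ", transition)
  if (!cn$enabledMask[k])
    .err("vhlG2P_state_error", "transition is knocked out: ", transition)
  m <- marking[cn$pid]
  if (!all(m[cn$ins[[k]]$idx] >= cn$ins[[k]]$w))
    .err("vhlG2P_state_error", "transition not enabled: ", transition)
  ii <- cn$ins[[k]]; oo <- cn$outs[[k]]
  if (length(ii$idx)) m[ii$idx] <- m[ii$idx] - ii$w
  if (length(oo$idx)) m[oo$idx] <- m[oo$idx] + oo$w
  stats::setNames(as.integer(m), cn$pid)
}

#' Knock out transitions
#'
#' Models a lost interaction by disabling the corresponding transition(s);
#' disabled transitions never fire. The original net is unmodified.
#'
#' @param net a [PetriNet-class].
#' @param transitions character vector of transition ids.
#' @return a new [PetriNet-class] with the ids added to the disabled set.
#' @export
knockout <- function(net, transitions) {
  unknown <- setdiff(transitions, net@transitions$id)
  if (length(unknown))
    .err("vhlG2P_input_error", "unknown transition id(s): ",
         paste(unknown, collapse = ", "))
  new("PetriNet", places = net@places, transitions = net@transitions,
      arcs = net@arcs, disabled = union(net@disabled, transitions))
}

#' Increment tokens of selected places
#'
#' Models constitutive activation (e.g. raising the tokens of the MAPK
#' activation place) by pointwise addition to a marking.
#'
#' @param marking named integer vector.
#' @param increments named vector of positive integers (place id -> tokens
#'   to add).
#' @return the perturbed marking.
#' @export
perturbMarking <- function(marking, increments) {
  if (!length(increments)) return(marking)
  unknown <- setdiff(names(increments), names(marking))
  if (length(unknown))
    .err("vhlG2P_input_error", "unknown place id(s): ",
         paste(unknown, collapse = ", "))
  marking[names(increments)] <- marking[names(increments)] +
    as.integer(increments)
  marking
}

#' Simulate a Petri net
#'
#' Token-game simulation under one of two policies.
#' \code{random_single_fire} (default): each step picks one enabled
#' transition uniformly at random (seeded) and fires it.
#' \code{maximal_step}: each step fires every enabled transition once, in
#' random order, skipping those no longer enabled. A step with no enabled
#' transition records a deadlock and holds the marking. Replicate r uses
#' seed \code{seed + r - 1}, so results are bit-reproducible.
#'
#' @param net a [PetriNet-class].
#' @param initial initial marking; default from the net spec.
#' @param steps simulation steps (default 2000).
#' @param replicates number of independent replicates (default 1).
#' @param seed base RNG seed (default 1).
#' @param policy \code{"random_single_fire"} or \code{"maximal_step"}.
#' @param recordEvery trajectory checkpoint interval (default steps/20).
#' @return a [PetriExperiment-class].
#' @export
simulateNet <- function(net, initial = initialMarking(net), steps = 2000L,
                        replicates = 1L, seed = 1L,
                        policy = c("random_single_fire", "maximal_step"),
                        recordEvery = max(1L, steps %/% 20L)) {
  policy <- match.arg(policy)
  if (steps < 1L || replicates < 1L)
    .err("vhlG2P_input_error", "steps and replicates must be >= 1")
  cn <- .compileNet(net)
  if (!all(names(initial) %in% cn$pid) || length(initial) != length(cn$pid))
    .err("vhlG2P_input_error", "marking domain must equal the place set")
  nT <- length(cn$tid)
  checkpoints <- seq(recordEvery, steps, by = recordEvery)
  finals <- matrix(0L, nrow = replicates, ncol = length(cn$pid),
                   dimnames = list(NULL, cn$pid))
  fires <- matrix(0L, nrow = replicates, ncol = nT,
                  dimnames = list(NULL, cn$tid))
  traj <- array(0, dim = c(length(cn$pid), length(checkpoints), replicates))
  deadlocks <- integer(replicates)
  for (r in seq_len(replicates)) {
    set.seed(seed + r - 1L)
    m <- as.integer(initial[cn$pid])
    ck <- 1L
    for (s in seq_len(steps)) {
      en <- which(vapply(seq_len(nT), function(k) {
        cn$enabledMask[k] && all(m[cn$ins[[k]]$idx] >= cn$ins[[k]]$w)
      }, logical(1)))
      if (!length(en)) {
        deadlocks[r] <- deadlocks[r] + 1L
      } else if (policy == "random_single_fire") {
        k <- if (length(en) == 1L) en else en[sample.int(length(en), 1L)]
        ii <- cn$ins[[k]]; oo <- cn$outs[[k]]
        if (length(ii$idx)) m[ii$idx] <- m[ii$idx] - ii$w
        if (length(oo$idx)) m[oo$idx] <- m[oo$idx] + oo$w
        fires[r, k] <- fires[r, k] + 1L
      } else {
        for (k in sample(en)) {
          ii <- cn$ins[[k]]
          if (!all(m[ii$idx] >= ii$w)) next
          oo <- cn$outs[[k]]
          if (length(ii$idx)) m[ii$idx] <- m[ii$idx] - ii$w
          if (length(oo$idx)) m[oo$idx] <- m[oo$idx] + oo$w
          fires[r, k] <- fires[r, k] + 1L
        }
      }
      if (ck <= length(checkpoints) && s == checkpoints[ck]) {
        traj[, ck, r] <- m
        ck <- ck + 1L
      }
    }
    finals[r, ] <- m
  }
  trajMean <- apply(traj, c(1, 2), mean)
  dimnames(trajMean) <- list(cn$pid, paste0("step_", checkpoints))
  new("PetriExperiment",
      summary = data.frame(place = cn$pid,
                           mean = colMeans(finals),
                           sd = apply(finals, 2, stats::sd),
                           stringsAsFactors = FALSE),
      firings = data.frame(transition = cn$tid,
                           mean_count = colMeans(fires),
                           stringsAsFactors = FALSE),
      trajectories = trajMean,
      config = list(steps = steps, replicates = replicates, seed = seed,
                    policy = policy, recordEvery = recordEvery,
                    disabled = net@disabled,
                    mean_deadlocks = mean(deadlocks)))
}

#' Final-marking summary accessor
#' @param x a [PetriExperiment-class].
#' @return data.frame with columns \code{place}, \code{mean}, \code{sd}.
#' @export
experimentSummary <- function(x) x@summary

#' Firing-count summary accessor
#' @param x a [PetriExperiment-class].
#' @return data.frame with columns \code{transition}, \code{mean_count}.
#' @export
experimentFirings <- function(x) x@firings

setMethod("show", "PetriExperiment", function(object) {
  cfg <- object@config
  cat("PetriExperiment:", cfg$steps, "steps x", cfg$replicates,
      "replicates |", cfg$policy, "| seed", cfg$seed, "\n")
  s <- object@summary
  s <- s[order(-s$mean), , drop = FALSE]
  for (i in seq_len(min(6L, nrow(s))))
    cat(sprintf("  %-24s mean %8.2f  sd %7.2f\n", s$place[i], s$mean[i],
                s$sd[i]))
  invisible(NULL)
})

setMethod("show", "PetriNet", function(object) {
  cat("PetriNet:", nrow(object@places), "places,",
      nrow(object@transitions), "transitions,", nrow(object@arcs), "arcs\n")
  if (length(object@disabled))
    cat("  knocked out:", paste(object@disabled, collapse = ", "), "\n")
  invisible(NULL)
})

#' Compare a perturbed experiment with wild-type
#'
#' Per place: difference in mean final tokens and log2 ratio with a
#' pseudocount of 1, ranked by absolute difference.
#'
#' @param wildType,perturbed [PetriExperiment-class] objects over the same
#'   place set.
#' @return data.frame with columns \code{place}, \code{wt_mean},
#'   \code{perturbed_mean}, \code{delta}, \code{log2_ratio}, ranked by
#'   |delta| descending.
#' @export
compareExperiments <- function(wildType, perturbed) {
  w <- wildType@summary; p <- perturbed@summary
  if (!setequal(w$place, p$place))
    .err("vhlG2P_input_error", "experiments cover different place sets")
  p <- p[match(w$place, p$place), , drop = FALSE]
  out <- data.frame(place = w$place, wt_mean = w$mean,
                    perturbed_mean = p$mean, delta = p$mean - w$mean,
                    log2_ratio = log2((p$mean + 1) / (w$mean + 1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$delta)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
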