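# shared fixtures built in code

# tiny mutation set with explicit fields
tinyMutations <- function() {
  MutationSet(
    variant = c("p.Arg167Trp", "p.Arg167Gln", "p.Tyr98His", "p.Ser65Leu",
                "p.Arg200Trp"),
    position = c(167L, 167L, 98L, 65L, 200L),
    wt_aa = c("R", "R", "Y", "S", "R"),
    mut_aa = c("W", "Q", "H", "L", "W"),
    n_patients = c(200L, 166L, 20L, 5L, 3L),
    phenotypes = list(c("renal_disease", "pheochromocytoma"),
                      c("renal_disease"),
                      c("hemangioblastoma_retinal"),
                      c("renal_disease"),
                      c("polycythemia")))
}

# write a small mutation TSV; returns the path
writeTinyTSV <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("variant\tn_patients\tphenotypes\tsource", rows), path)
  path
}

# concatenate two MutationSets
rbindMs <- function(a, b) {
  MutationSet(variant = c(mutationTable(a)$variant, mutationTable(b)$variant),
              position = c(mutationPositions(a), mutationPositions(b)),
              wt_aa = c(mutationTable(a)$wt_aa, mutationTable(b)$wt_aa),
              mut_aa = c(mutationTable(a)$mut_aa, mutationTable(b)$mut_aa),
              n_patients = c(patientCounts(a), patientCounts(b)),
              phenotypes = c(mutationPhenotypes(a), mutationPhenotypes(b)))
}

# independent quantile oracle: sort + linear interpolation (type-7 formula)
oracleQuantile <- function(x, p) {
  x <- sort(as.numeric(x))
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# random small Petri net for property tests (pure function of seed)
randomNet <- function(seed) {
  set.seed(seed)
  nP <- sample(3:6, 1); nT <- sample(2:5, 1)
  pid <- paste0("p", seq_len(nP)); tid <- paste0("t", seq_len(nT))
  arcs <- do.call(rbind, lapply(tid, function(t) {
    nin <- sample(0:2, 1); nout <- sample(1:2, 1)
    rbind(
      if (nin > 0)
        data.frame(from = sample(pid, nin), to = t,
                   weight = sample(1:2, nin, replace = TRUE),
                   stringsAsFactors = FALSE),
      data.frame(from = t, to = sample(pid, nout),
                 weight = sample(1:2, nout, replace = TRUE),
                 stringsAsFactors = FALSE))
  }))
  buildNet(list(
    places = data.frame(id = pid, label = pid,
                        initial = sample(0:3, nP, replace = TRUE),
                        stringsAsFactors = FALSE),
    transitions = data.frame(id = tid, label = tid, stringsAsFactors = FALSE),
    arcs = arcs))
}

# brute-force enabled-transition oracle working directly off the arc table
oracleEnabled <- function(net, marking) {
  tid <- net@transitions$id
  a <- net@arcs
  ok <- vapply(tid, function(t) {
    if (t %in% net@disabled) return(FALSE)
    inn <- a[a$to == t, , drop = FALSE]
    all(marking[inn$from] >= inn$weight)
  }, logical(1))
  tid[ok]
}

# rigid-body transform of a structure's coordinates
rotateStructure <- function(st, angle = 0.7, shift = c(5, -3, 2)) {
  a <- structureAtoms(st)
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  ProteinStructure(a)
}
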