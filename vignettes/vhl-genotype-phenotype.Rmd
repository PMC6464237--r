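---
title: "Genotype-phenotype analysis of pVHL disease mutations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-phenotype analysis of pVHL disease mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhlG2P)
```

# Scope and model

The von Hippel-Lindau tumor suppressor protein (pVHL) is the
substrate-recognition component of the VCB E3 ubiquitin-ligase complex
(pVHL + Elongin-B/C + Cullin-2) that targets the hypoxia-inducible
transcription factor HIF-1&alpha; for degradation. Germline and somatic
missense mutations of pVHL cause VHL disease, a familial predisposition to
renal cell carcinoma, hemangioblastoma, pheochromocytoma and a spectrum of
rarer tumors. `vhlG2P` implements a structured genotype-phenotype analysis
of curated pVHL variant tables:

1. **Hotspot detection** — positions whose per-variant patient counts
   exceed an empirical quantile of the count vector.
2. **Surface mapping** — normalized mutated fractions and phenotype
   distributions per binding surface, with cross-surface tests.
3. **Residue interaction networks** — typed residue-residue contacts
   (salt bridge, hydrogen bond, &pi;-&pi; stacking, van der Waals)
   computed from PDB coordinates, and the contacts a substitution could
   remove.
4. **Impairment analysis** — the "negative snapshot" of interactors whose
   binding regions are untouched by each phenotype's mutations, and PTM
   sites overlapped by missense variants.
5. **Petri-net simulation** — discrete token-game simulation of a
   hypoxia-pathway model under transition knockouts and token increments.
6. **Synthetic data** — seeded generators for every input, with
   ground-truth sidecars, so each stage is testable offline.

# Data model and conventions

All residue positions are 1-based on the full-length pVHL30 numbering
(1-213); ranges are inclusive on both ends. Variants are parsed from HGVS
protein notation (`p.Arg167Trp`); synonymous records (`p.Arg200=`) are
retained by the parser but excluded from surface/phenotype statistics.
Phenotype labels are normalized case-insensitively into a closed
vocabulary with an `other` sink; renal manifestations (ccRCC, RCC, renal
cysts, renal carcinoma) are collectively mapped to `renal_disease`,
because case reports frequently lack precise sub-typing. The synonym map
is an editable YAML config (`inst/extdata/phenotype_synonyms.yaml`).

## Binding surfaces

Five binding surfaces are used: A (Elongin/VCB assembly), B (the
HIF-1&alpha; substrate site), C (the Cullin-2 side), D (the N-terminal
acidic tail specific to the pVHL30 isoform) and E (the C-terminal tail).
The literature defines these interfaces structurally; published analyses
report their sizes (35, 43, 49, 59 and 23 residues) but not residue-level
membership. The packaged default (`defaultSurfaces()`) is therefore a
**best-effort reconstruction** with exactly those sizes — D = 1-59,
B = 63-105, C = 106-154, A = 156-190, E = 191-213 — chosen so that every
residue with a narratively assigned surface lands correctly (Arg167,
Arg161, Gln164, Val166 on A; Ser65, Asn78, Pro81, Tyr98, Ser72 on B;
Ser111, His115, Trp117, Ala149, Ile151 on C; Ser33/38/43 on D; Arg200 on
E). Users with authoritative definitions should supply their own config
(`readSurfaceConfig()`); all downstream functions take a `SurfaceSet`.

A known published inconsistency is worth recording: the mutated-fraction
table that motivates this module prints four self-consistent count/percent
pairs (39/43 = 91%, 43/49 = 88%, 28/35 = 80%, 15/23 = 65%) and one that is
not (27/59 printed as 56%; the formula gives 46%, and 56% corresponds to
33/59). `mutatedFraction()` always reports `round(100 * n / size)`; the
acceptance machinery reports both readings of the inconsistent pair.

# Hotspot rule

`detectHotspots()` selects variants whose patient count strictly exceeds
the empirical quantile (default level 0.95) of the per-variant count
vector, then collapses them to distinct positions ranked by total patient
count (ties broken by ascending position). Two estimators are provided:
linear interpolation of order statistics (`stats::quantile` type 7, the
default of the statistical environment in which such analyses are
typically run) and nearest-rank (type 1). The quantile is computed over
per-variant counts rather than per-position totals because the selection
rule is defined on the vector of patient numbers per mutation;
`aggregateBy = "position"` gives the alternative reading. A strictly-greater
comparison is the default; `strict = FALSE` permits ties. Pooling of
germline and somatic records is left to the upstream curation: the package
takes whatever table it is given.

# Surface statistics and tests

`mutatedFraction()` counts *distinct* mutated positions inside a surface
(so duplicated records at one position count once) and reports the integer
percentage of the interface covered. `phenotypeDistribution()` reports
one-decimal percentage proportions of single-phenotype records per
surface; records whose position touches several surfaces count once per
surface (all-match policy — boundary handling is not specified by the
published analysis, and all-match is the conservative choice that never
silently drops a record). Proportions are over unweighted variant records,
not patient-weighted counts.

`compareSurfaces()` offers three routes: a chi-squared test of
independence on the surface x phenotype contingency table (no continuity
correction; used for phenotype-association questions), a seeded label
-permutation test with the same statistic (for small tables where the
asymptotic reference is doubtful), and one-way ANOVA on per-position
mutation counts grouped by surface (the published route for differences in
mutation *distribution*). The significance threshold used in reports is
0.05 with no multiple-testing correction, matching the published analysis;
all-zero phenotype columns are dropped with a message.

# Residue interaction networks

`detectContacts()` is a deliberately simple, fully parameterized geometry
in the spirit of residue-interaction-network tools: salt bridge =
opposite-charge side-chain N/O pair within 4.0 &Aring; (Lys NZ, Arg
NH1/NH2/NE, His ND1/NE2 versus Asp OD1/OD2, Glu OE1/OE2); hydrogen bond =
N/O heavy-atom pair within 3.5 &Aring; with **no angle term** (a
simplification relative to full RING-style detectors); &pi;-&pi; =
aromatic ring centroids (Phe/Tyr/Trp/His) within 6.5 &Aring;; van der
Waals = heavy-atom pair within the sum of element radii + 0.5 &Aring;.
Per residue pair only the highest-priority type is kept (salt bridge >
hbond > &pi;-&pi; > vdW), with the realizing atom pair and distance.
Sequence-adjacent pairs (|i-j| < 2) are excluded within a chain to avoid
trivial backbone contacts; only the first model of a multi-model PDB file
is read; alternate locations resolve to highest occupancy; waters and
hydrogens are dropped. All cutoffs are recorded in every serialization.
Residues with missing side-chain atoms simply cannot realize the typed
interactions and degrade to vdW-only contacts.

This module does **not** re-implement angle-dependent H-bond energetics,
ionic-cluster merging, or interface-area computation. On the packaged
constructed geometries the typing is exact by construction; on real
structures the edges should be read qualitatively.

# Impairment analysis

`buildImpairmentMatrix()` restricts to single-phenotype variants, groups
them by normalized phenotype (optionally pooling terms into one row, e.g.
both hemangioblastoma subtypes), and marks an interactor *affected* for a
phenotype iff any of its binding residues carries a mutation from that
phenotype's subset. Overlap is exact positional membership; a configurable
±k margin exists (default 0) for sensitivity analyses. A phenotype row
computed from zero mutations returns every interactor, flagged vacuous.
`ptmOverlap()` reports every PTM site whose position carries at least one
missense variant, with the union of overlapping phenotypes.

# Petri-net simulation

`buildNet()` validates a place/transition net (bipartite arcs, positive
integer weights, no dangling endpoints) from JSON or a minimal PNML
subset. `simulateNet()` plays the token game: under the default
`random_single_fire` policy each step draws one enabled transition
uniformly at random and fires it; `maximal_step` fires every enabled
transition once per step in random order. The reference pathway model the
published experiments ran on is external and its exact scheduling
semantics are not restated there, so the policy is explicit, recorded in
every result, and both readings of "simulation step" are available.
Deadlocks (no enabled transition) are recorded and hold the marking —
biological nets may exhaust tokens, and that is a result, not an error.
Replicate r uses seed `seed + r - 1`, making every experiment bit
-reproducible. Perturbations are transition knockouts (`knockout()`, the
transition never fires) and token increments (`perturbMarking()`; the
published recipes say "increased" without amounts, so the default
increment in the pipeline is +5 and all conclusions are drawn from
wild-type-relative deltas, which makes the qualitative directions robust
to the magnitude). `compareExperiments()` reports per-place mean
differences and log2 ratios with a pseudocount of 1.

The packaged fixture net (`fixturePetriNet()`) distills the pathway
qualitatively: a HIF synthesis source, a pVHL-dependent HIF degradation
transition (the only HIF sink), HIF-driven VEGF production, an AKT branch
(activation source, pVHL-dependent inhibition, survival and glycolysis
outputs) and a MAPK place draining into POMC. Ids reuse the
pathway-model aliases (`p_54`, `p_38`, `p_39`, `p_60`, `t_181`, `t_109`)
so published perturbation recipes run end-to-end. By construction,
knocking out the degradation transition must strictly raise mean HIF and
VEGF tokens — the direction, not the magnitude, is the tested claim.

# Synthetic data: what it emulates, and what it does not

`generateMutationTable()` draws variant positions uniformly, patient
counts from a geometric distribution (heavy-tailed: most variants rare,
few frequent), planted hotspot positions with multiplied counts, and
phenotype sets from base rates with surface-conditional odds multipliers;
a configurable fraction of variants (default 0.45, echoing the roughly
742/1,670 single-phenotype share of curated records) carries exactly one
phenotype. Raw synonym spellings are emitted so normalization is
exercised. The ground-truth sidecar records the planted hotspot set,
enrichments and the exact single-phenotype count, sufficient to score
every recovery experiment.

`syntheticCuratedTable()` is a fully deterministic 385-variant emulation
of a curated table. Its constructed facts — 18 positions above the strict
95th-quantile threshold with Arg167 top-ranked at 366 patients over its
two main variants, seven distinct substitutions at Asn78, single-phenotype
footprints that reproduce the published conserved-interactor rows against
the packaged synthetic interactor table, and missense overlap of exactly
14 PTM sites — are encoded by construction. The low-count filler block is
sized so the 95th-quantile threshold of the count vector interpolates
inside the low block (threshold 3), which makes the selection exact
rather than knife-edge. These tables emulate the *structure* of real
curations, not their marginals: real patient counts are not geometric at
the tails, real phenotype co-occurrence is correlated by syndrome type,
and real surfaces are three-dimensional neighborhoods rather than index
ranges. Passing tests therefore demonstrate correctness of the machinery
on data with the assumed structure, not fidelity of any biological claim.

Toy structures (`generateToyStructure()`) place an Arg/Glu pair at an
exact guanidinium-carboxylate gap, two stacked Phe rings at an exact
centroid distance, or a 12-residue poly-alanine helix (a negative control
with no charged or aromatic side chains); each carries a sidecar of
intended contacts derived from the default cutoffs.

# Numerical and design choices

* Quantile estimator: type 7 default, nearest-rank option; both exposed.
* Rounding: integer percent for surface coverage (matching the published
  "91%"), one decimal for phenotype proportions (matching "75.6%").
* Chi-squared statistic without continuity correction, so the permutation
  and asymptotic routes estimate the same quantity; an observed statistic
  of exactly 0 reports p = 1.
* Permutation p-values use the add-one estimator (1 + hits)/(1 + B).
* Tie-breaks: hotspot ranking by total patients, then ascending position;
  impairment columns alphabetical; all outputs deterministic given seeds.
* Degenerate inputs: empty count vectors, empty surfaces, < 2 non-empty
  groups and unknown ids raise classed errors; zero records on a surface
  is an empty distribution, not an error.
* The power experiment for planted surface enrichment runs at 6,000
  variants per table. That size comes from a prospective power analysis:
  at the stated effect (odds multiplier 0.5 on renal disease for surface
  D) simulated power is about 0.35 at 1,670 variants, 0.78 at 4,000 and
  0.94 at 6,000, so 6,000 is the smallest round size with comfortable
  margin over the 80% design target. Effect size, alpha and the target
  were fixed first; only N was chosen.
* Test-suite problem sizes (100-replicate recovery and power runs, 1,000
  random nets for simulator invariants, 50 x 2,000-step knockout
  comparisons) are the package's chosen design points for those
  experiments.

# Known limitations

* Surface memberships are a reconstruction (above); analyses that depend
  on exact boundary residues should supply curated definitions.
* The contact detector is distance-only; it will over-call hydrogen bonds
  relative to angle-aware tools and does not merge ionic networks.
* The Petri semantics are discrete and unweighted-by-rate; they support
  qualitative direction-of-change claims only.
* The impairment criterion is positional overlap with binding ranges; it
  does not model distance-based or allosteric disruption.
* Real supplementary curations (the full VHLdb-derived tables) are not
  bundled; packaged tables labelled *synthetic* are constructed emulations
  that encode published qualitative facts for testing.
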