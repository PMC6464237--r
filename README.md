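# vhlG2P

Genotype-phenotype analysis of disease mutations of the von Hippel-Lindau
tumor suppressor protein (pVHL).

pVHL is the substrate-recognition subunit of the VCB E3 ubiquitin-ligase
complex (pVHL + Elongin-B/C + Cullin-2) that degrades the hypoxia-inducible
transcription factor HIF-1α. Missense mutations of pVHL cause VHL disease —
a familial predisposition to renal cell carcinoma, cerebellar and retinal
hemangioblastoma, pheochromocytoma and rarer tumors — and the *position* of
a mutation on the protein's binding surfaces carries information about the
phenotype it produces. `vhlG2P` is for computational biologists who curate
or analyse pVHL variant tables and want the full analysis chain as tested,
scriptable R functions.

## What it computes

* **Mutation hotspots.** A variant is a hotspot candidate when its patient
  count *n* exceeds the empirical quantile of the per-variant count vector:
  select variants with *n* > Q̂<sub>0.95</sub>(n₁, …, n<sub>m</sub>)
  (linear-interpolation estimator; nearest-rank optional), then collapse to
  positions ranked by total patients.
* **Surface mapping.** For each binding surface *S* (A: Elongin/VCB, B:
  HIF-1α site, C: Cullin-2 side, D: pVHL30 N-terminal tail, E: C-terminal
  tail), the normalized mutated fraction 100·|mutated positions ∩ S|/|S|,
  and phenotype distributions of single-phenotype variants, with χ²,
  permutation and ANOVA cross-surface tests.
* **Residue interaction networks.** Typed contacts from PDB coordinates —
  salt bridge (opposite-charge side-chain N/O ≤ 4.0 Å), hydrogen bond
  (N/O pair ≤ 3.5 Å), π-π (aromatic ring centroids ≤ 6.5 Å), van der
  Waals (radii sum + 0.5 Å) — one highest-priority edge per residue pair,
  plus the edges a substitution would remove.
* **Impairment snapshots.** Per phenotype, the interactors whose
  binding-interface residues contain none of that phenotype's mutation
  positions (conserved interactions), and PTM sites overlapped by missense
  variants.
* **Petri-net perturbation.** Seeded token-game simulation of a
  place/transition pathway model under transition knockouts and token
  increments, with per-place wild-type-versus-perturbed deltas.
* **Synthetic data.** Seeded generators (mutation tables with planted
  hotspots and surface enrichments, toy structures with known contacts, a
  miniature hypoxia net) with ground-truth sidecars.

## Worked example

```r
library(vhlG2P)

ms <- syntheticCuratedTable()       # deterministic curated-scale emulation
ms
#> MutationSet with 385 variant records
#>   positions: 1 - 213 | patients total: 2094 | synonymous: 0
#>   top phenotypes: renal_disease, pheochromocytoma, hemangioblastoma_cerebellar, ...

hs <- detectHotspots(ms, level = 0.95, strict = TRUE)
head(hs, 3)
#>   position total_patients n_distinct_variants variants
#> 1      167            366                   2      Q,W
#> 2       78            150                   1        S
#> 3       98            140                   1        H
```

Eighteen positions exceed the strict 95th-quantile threshold (here 3
patients); position 167 leads with 366 patients over its two variants —
the Arg167Trp/Arg167Gln pair on surface A, whose loss destabilizes VCB
complex assembly.

```r
im <- buildImpairmentMatrix(ms, syntheticInteractors(),
  groups = list(pheochromocytoma = "pheochromocytoma",
                hemangioblastoma = c("hemangioblastoma_cerebellar",
                                     "hemangioblastoma_retinal")))
im
#> ImpairmentMatrix: 2 phenotypes x 15 interactors
#>   pheochromocytoma             unaffected: AKT1, HSPA4
#>   hemangioblastoma             unaffected: E2F1, ELAVL1, ELOC, ID2, TP53
```

Pheochromocytoma-only mutations leave the AKT1 and HSPA4 binding regions
untouched (those interactions are retained), while hemangioblastoma-only
mutations spare the transcription-regulator set.

```r
net <- buildNet(fixturePetriNet())
wt <- simulateNet(net, steps = 2000, replicates = 50, seed = 1)
ko <- simulateNet(knockout(net, "t_181"), steps = 2000, replicates = 50, seed = 1)
head(compareExperiments(wt, ko), 3)
#>          place wt_mean perturbed_mean   delta log2_ratio
#> 1          HIF   19.30         343.28  323.98  4.0840307
#> 2 HIF_degraded  280.20           0.00 -280.20 -8.1354528
#> 3         VEGF  281.38         340.46   59.08  0.2740787
```

Knocking out the pVHL-dependent HIF degradation transition removes the
only HIF sink: mean HIF tokens rise from ~19 to ~343 after 2,000 steps,
dragging VEGF production up with them — the token-level picture of
pseudo-hypoxic signaling after pVHL loss.

The full chain (parse → hotspots → surfaces → network → impairment →
Petri) runs through `runPipeline()`, which writes per-stage TSV/JSON and a
manifest with seeds and input checksums.

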