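Package: vhlG2P
Title: Genotype-Phenotype Analysis of von Hippel-Lindau Tumor Suppressor Mutations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing disease mutations of the von Hippel-Lindau tumor
    suppressor protein (pVHL): detection of mutation hotspots by a patient-count
    quantile rule, mapping of phenotype-associated missense variants onto pVHL
    binding surfaces with per-surface phenotype distributions and cross-surface
    tests, typed residue-residue interaction networks computed from 3D structures
    (hydrogen bonds, salt bridges, van der Waals contacts, pi-pi stacking),
    conserved-interactor ("negative snapshot") and PTM-overlap analyses, and
    discrete place/transition (Petri) net simulation of hypoxia-pathway
    perturbations via transition knockouts and token increments. A synthetic-data
    module generates mutation tables with planted hotspots and surface
    enrichments, toy structures with known contacts, and a miniature
    hypoxia-response net, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    xml2,
    bio3d,
    igraph
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, StructuralPrediction, NetworkInference, SystemsBiology,
    VariantAnnotation
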