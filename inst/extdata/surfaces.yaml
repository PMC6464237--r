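# pVHL binding-surface definitions on full-length pVHL30 numbering (1-213).
# Inclusive 1-based ranges. Sizes: A=35, B=43, C=49, D=59, E=23.
# Residue memberships are a best-effort reconstruction consistent with the
# residues named in the genotype-phenotype narrative; edit to override.
A: ["156-190"]
B: ["63-105"]
C: ["106-154"]
D: ["1-59"]
E: ["191-213"]
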