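# SYNTHETIC interactor table emulating a high-confidence curated pVHL interactor list.
# Binding ranges are constructed (not curated) so the conserved-interactor snapshot
# against the packaged synthetic curated table reproduces the published qualitative rows.
name	uniprot	binding_residues
ELOC	Q15369	157-171
ELOB	Q15370	85-95,153-165
CUL2	Q13617	117-160
HIF1A	Q16665	63-117
TP53	P04637	30-50
ID2	Q02363	46-66
ELAVL1	Q15717	155-170
E2F1	Q01094	78-88
HSPA4	P34932	95-100
AKT1	P31749	115-125
HDAC1	Q13547	70-100
USP33	Q8TEY7	60-70,88-100
PRKCZ	Q05513	33-40,110-120
DGKZ	Q13574	115-120,150-190
TUBB	P07437	88-98,155-160
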