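# SYNTHETIC PTM-site table emulating the curated pVHL PTM catalogue.
# NEK1 phosphorylation-site positions are synthetic placements on surfaces B/C.
position	type	enzyme
33	phosphorylation	CSNK2A1
38	phosphorylation	CSNK2A1
43	phosphorylation	CSNK2A1
68	phosphorylation	GSK3B
72	phosphorylation	AURKA
111	phosphorylation	CHEK2
75	phosphorylation	NEK1
89	phosphorylation	NEK1
101	phosphorylation	NEK1
112	phosphorylation	NEK1
122	phosphorylation	NEK1
134	phosphorylation	NEK1
146	phosphorylation	NEK1
159	neddylation	NEDD8
171	sumoylation	PIAS4
79	methylation	PRMT1
82	methylation	PRMT1
155	ubiquitination	-
196	ubiquitination	-
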