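# Raw literature label -> controlled vocabulary term (case-insensitive).
# Renal manifestations are collectively presented as renal disease.
renal_disease:
  - ccRCC
  - RCC
  - renal cell carcinoma
  - clear cell renal cell carcinoma
  - renal carcinoma
  - renal cyst
  - renal cysts
  - benign renal cancer
  - renal disease
pheochromocytoma:
  - pheochromocytoma
  - phaeochromocytoma
hemangioblastoma_cerebellar:
  - cerebellar hemangioblastoma
  - CNS hemangioblastoma
  - central nervous system hemangioblastoma
  - cerebellar HB
hemangioblastoma_retinal:
  - retinal hemangioblastoma
  - retinal angioma
  - retinal HB
paraganglioma:
  - paraganglioma
pnet:
  - PNET
  - pancreatic neuroendocrine tumor
  - pancreatic neuroendocrine tumour
pancreatic_cyst:
  - pancreatic cyst
  - pancreatic cysts
  - pancreatic lesion
polycythemia:
  - polycythemia
  - polycythaemia
  - erythrocytosis
elst:
  - ELST
  - endolymphatic sac tumor
  - endolymphatic sac tumour
colorectal_cancer:
  - colorectal cancer
  - colorectal carcinoma
glial_tumor:
  - glial tumor
  - glial tumour
  - glioma
cystadenoma:
  - cystadenoma
  - epididymal cystadenoma
  - ovarian cystadenoma
si_net:
  - SI-NET
  - small intestine neuroendocrine tumor
other:
  - other
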