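protein_id	group_label
KRT1	keratins
KRT2	keratins
KRT3	keratins
KRT5	keratins
KRT6A	keratins
KRT7	keratins
KRT8	keratins
KRT10	keratins
KRT14	keratins
KRT15	keratins
KRT16	keratins
KRT17	keratins
KRT19	keratins
KRT23	keratins
KRT26	keratins
KRT27	keratins
KRT28	keratins
KRT73	keratins
KRT75	keratins
KRT80	keratins
PSMA5	proteasome
PSMA6	proteasome
PSMB1	proteasome
PSMB6	proteasome
DSG1	corneodesmosome
DSC1	corneodesmosome
ASPRV1	filaggrin_processing
CAPNS1	filaggrin_processing
BLMH	filaggrin_processing
CASP14	filaggrin_processing
ARG1	filaggrin_processing
HAL	filaggrin_processing
GGCT	filaggrin_processing
SBSN	CE_processing
ASAH1	CE_processing
ALOX12B	CE_processing
ALOXE3	CE_processing
SERPINB8	CE_processing
FLNA	cytoskeleton
FLNB	cytoskeleton
TTN	cytoskeleton
ARHGEF17	cytoskeleton
VIM	cytoskeleton
GFAP	cytoskeleton
GGH	redox
PRDX2	redox
GAPDH	metabolism
HSPA5	protein_quality_control
NPEPPS	protein_quality_control
SRP68	protein_quality_control
ACVR2A	signalling
GSDMA	barrier_markers
ANXA2	barrier_markers
LAMA2	basement_membrane
SBNO1	other
EN2	other
NCCRP1	other
MUC16	other
NAV1	other
P_K1C10	keratins
P_SBSN	CE_processing
P_VIM	cytoskeleton
P_ASPRV1	filaggrin_processing
P_ANXA2	barrier_markers
P_HBB	blood
P_S100A7	inflammation
P_S100A9	inflammation
P_HSPA8	protein_quality_control
P_TUFT1	other
P_CALML5	calcium_binding
P_IL37	inflammation
P_SERPINB2	other
P_PGK1	metabolism
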