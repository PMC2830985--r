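probe_set	accession	description	gene	symbol	intensity_1	call_1
bmp4_at	FX12159	bone morphogenetic protein 4	12159	Bmp4	1335	P
ccl2_at	FX20296	chemokine (C-C motif) ligand 2	20296	Ccl2	239	P
ccl25_at	FX20300	chemokine (C-C motif) ligand 25	20300	Ccl25	123	P
cd80_at	FX12519	CD80 antigen	12519	Cd80	462	P
cxcl12_at	FX20315	chemokine (C-X-C motif) ligand 12	20315	Cxcl12	12222	P
ereg_at	FX13874	epiregulin	13874	Ereg	422	P
igf2r_at	FX16004	insulin-like growth factor 2 receptor	16004	Igf2r	535	P
il7_at	FX16196	interleukin 7	16196	Il7	189	P
jam2_at	FX67374	junction adhesion molecule 2	67374	Jam2	201	P
jam3_at	FX83964	junction adhesion molecule 3	83964	Jam3	152	P
ncam1_at	FX17967	neural cell adhesion molecule 1	17967	Ncam1	129	P
osmr_at	FX18414	oncostatin M receptor	18414	Osmr	1151	P
pdgfra_at	FX18595	platelet derived growth factor receptor, alpha polypeptide	18595	Pdgfra	2140	P
pdgfrb_at	FX18596	platelet derived growth factor receptor, beta polypeptide	18596	Pdgfrb	1829	P
tgfa_at	FX21802	transforming growth factor alpha	21802	Tgfa	261	P
vcam1_at	FX22329	vascular cell adhesion molecule 1	22329	Vcam1	692	P
vegfa_at	FX22339	vascular endothelial growth factor A	22339	Vegfa	275	P
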