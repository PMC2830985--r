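probe_set	accession	description	gene	symbol	intensity_1	call_1
bmp4_at	FX12159	bone morphogenetic protein 4	12159	Bmp4	1335	P
bmpr1a_at	FX12166	bone morphogenetic protein receptor, type 1A	12166	Bmpr1a	497	P
cxcl12_at	FX20315	chemokine (C-X-C motif) ligand 12	20315	Cxcl12	12222	P
ereg_at	FX13874	epiregulin	13874	Ereg	422	P
igf2r_at	FX16004	insulin-like growth factor 2 receptor	16004	Igf2r	535	P
il7_at	FX16196	interleukin 7	16196	Il7	189	P
jam2_at	FX67374	junction adhesion molecule 2	67374	Jam2	201	P
jam3_at	FX83964	junction adhesion molecule 3	83964	Jam3	152	P
osmr_at	FX18414	oncostatin M receptor	18414	Osmr	1151	P
tgfa_at	FX21802	transforming growth factor alpha	21802	Tgfa	261	P
tnfrsf1a_at	FX21937	tumor necrosis factor receptor superfamily, member 1a	21937	Tnfrsf1a	1974	P
tnfrsf1b_at	FX21938	tumor necrosis factor receptor superfamily, member 1b	21938	Tnfrsf1b	108	P
vcam1_at	FX22329	vascular cell adhesion molecule 1	22329	Vcam1	692	P
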