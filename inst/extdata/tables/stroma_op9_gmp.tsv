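probe_set	accession	description	gene	symbol	intensity_1	call_1
cxcl12_at	FX20315	chemokine (C-X-C motif) ligand 12	20315	Cxcl12	12222	P
ereg_at	FX13874	epiregulin	13874	Ereg	422	P
il7_at	FX16196	interleukin 7	16196	Il7	189	P
jam2_at	FX67374	junction adhesion molecule 2	67374	Jam2	201	P
jam3_at	FX83964	junction adhesion molecule 3	83964	Jam3	152	P
tgfa_at	FX21802	transforming growth factor alpha	21802	Tgfa	261	P
vcam1_at	FX22329	vascular cell adhesion molecule 1	22329	Vcam1	692	P
vegfa_at	FX22339	vascular endothelial growth factor A	22339	Vegfa	179	P
vegfb_at	FX22340	vascular endothelial growth factor B	22340	Vegfb	174	P
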