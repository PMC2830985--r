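probe_set	accession	description	gene	symbol	intensity_1	call_1
bmp4_at	FX12159	bone morphogenetic protein 4	12159	Bmp4	252	P
bmpr1a_at	FX12166	bone morphogenetic protein receptor, type 1A	12166	Bmpr1a	384	P
cxcl12_at	FX20315	chemokine (C-X-C motif) ligand 12	20315	Cxcl12	798	P
ereg_at	FX13874	epiregulin	13874	Ereg	153	P
igf2r_at	FX16004	insulin-like growth factor 2 receptor	16004	Igf2r	1704	P
jam2_at	FX67374	junction adhesion molecule 2	67374	Jam2	26	P
jam3_at	FX83964	junction adhesion molecule 3	83964	Jam3	204	P
notch3_at	FX18131	Notch gene homolog 3 (Drosophila)	18131	Notch3	48	P
osmr_at	FX18414	oncostatin M receptor	18414	Osmr	131	P
tgfa_at	FX21802	transforming growth factor alpha	21802	Tgfa	21	P
vcam1_at	FX22329	vascular cell adhesion molecule 1	22329	Vcam1	929	P
vegfa_at	FX22339	vascular endothelial growth factor A	22339	Vegfa	169	P
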