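probe_set	accession	description	gene	symbol	intensity_1	call_1
cxcl12_at	FX20315	chemokine (C-X-C motif) ligand 12	20315	Cxcl12	23	P
ereg_at	FX13874	epiregulin	13874	Ereg	288	P
il7_at	FX16196	interleukin 7	16196	Il7	92	P
jam2_at	FX67374	junction adhesion molecule 2	67374	Jam2	16	P
jam3_at	FX83964	junction adhesion molecule 3	83964	Jam3	42	P
ltbr_at	FX17000	lymphotoxin B receptor	17000	Ltbr	285	P
odc-rs_at	FX70458	Similar to Ornithine decarboxylase (ODC)	70458	Odc-rs	146	P
tgfa_at	FX21802	transforming growth factor alpha	21802	Tgfa	13	P
tgfbr2_at	FX21813	transforming growth factor, beta receptor II	21813	Tgfbr2	85	P
tgfbr3_at	FX21814	transforming growth factor, beta receptor III	21814	Tgfbr3	3429	P
tnfrsf1a_at	FX21937	tumor necrosis factor receptor superfamily, member 1a	21937	Tnfrsf1a	959	P
tnfrsf1b_at	FX21938	tumor necrosis factor receptor superfamily, member 1b	21938	Tnfrsf1b	721	P
vcam1_at	FX22329	vascular cell adhesion molecule 1	22329	Vcam1	182	P
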