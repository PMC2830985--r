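probe_set	accession	description	gene	symbol	intensity_1	call_1
acvr2b_at	FX11481	activin receptor IIB	11481	Acvr2b	166	P
bmp15_at	FX12155	Bone morphogenetic protein 15	12155	Bmp15	645	P
ccr9_at	FX12769	chemokine (C-C motif) receptor 9	12769	Ccr9	443	P
cxcr4_at	FX12767	chemokine (C-X-C motif) receptor 4	12767	Cxcr4	2121	P
egfr_at	FX13649	epidermal growth factor receptor	13649	Egfr	193	P
igf2_at	FX16002	insulin-like growth factor 2	16002	Igf2	282	P
il1r1_at	FX16177	interleukin 1 receptor, type I	16177	Il1r1	180	P
il1r2_at	FX16178	interleukin 1 receptor, type II	16178	Il1r2	127	P
il2rg_at	FX16186	interleukin 2 receptor, gamma chain	16186	Il2rg	3021	P
itga4_at	FX16401	Integrin alpha 4	16401	Itga4	1982	P
itgb2_at	FX16414	integrin beta 2	16414	Itgb2	920	P
osm_at	FX18413	oncostatin M	18413	Osm	112	P
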