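probe_set	accession	description	gene	symbol	intensity_1	call_1
acvr2b_at	FX11481	activin receptor IIB	11481	Acvr2b	183	P
bmp15_at	FX12155	Bone morphogenetic protein 15	12155	Bmp15	413	P
bmp4_at	FX12159	bone morphogenetic protein 4	12159	Bmp4	112	P
cxcr4_at	FX12767	chemokine (C-X-C motif) receptor 4	12767	Cxcr4	264	P
egfr_at	FX13649	epidermal growth factor receptor	13649	Egfr	231	P
igf2_at	FX16002	insulin-like growth factor 2	16002	Igf2	271	P
il1r1_at	FX16177	interleukin 1 receptor, type I	16177	Il1r1	123	P
itga4_at	FX16401	Integrin alpha 4	16401	Itga4	278	P
itgb1_at	FX16412	integrin beta 1 (fibronectin receptor beta)	16412	Itgb1	180	P
itgb2_at	FX16414	integrin beta 2	16414	Itgb2	507	P
osm_at	FX18413	oncostatin M	18413	Osm	157	P
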