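probe_set	accession	description	gene	symbol	intensity_1	call_1
cxcr4_at	FX12767	chemokine (C-X-C motif) receptor 4	12767	Cxcr4	1275	P
egfr_at	FX13649	epidermal growth factor receptor	13649	Egfr	145	P
il2rg_at	FX16186	interleukin 2 receptor, gamma chain	16186	Il2rg	2746	P
itga4_at	FX16401	Integrin alpha 4	16401	Itga4	1640	P
itgb1_at	FX16412	integrin beta 1 (fibronectin receptor beta)	16412	Itgb1	235	P
itgb2_at	FX16414	integrin beta 2	16414	Itgb2	1781	P
itgb7_at	FX16421	integrin beta 7	16421	Itgb7	942	P
lta_at	FX16992	lymphotoxin A	16992	Lta	540	P
tgfb1_at	FX21803	transforming growth factor, beta 1	21803	Tgfb1	718	P
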