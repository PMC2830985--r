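probe_set	accession	description	gene	symbol	intensity_1	call_1
acvr1_at	FX11477	activin A receptor, type 1	11477	Acvr1	107	P
acvr2a_at	FX11480	activin receptor IIA	11480	Acvr2a	131	P
bmp4_at	FX12159	bone morphogenetic protein 4	12159	Bmp4	277	P
cxcr4_at	FX12767	chemokine (C-X-C motif) receptor 4	12767	Cxcr4	290	P
egfr_at	FX13649	epidermal growth factor receptor	13649	Egfr	189	P
igf2_at	FX16002	insulin-like growth factor 2	16002	Igf2	139	P
il2rg_at	FX16186	interleukin 2 receptor, gamma chain	16186	Il2rg	2115	P
itga4_at	FX16401	Integrin alpha 4	16401	Itga4	268	P
itgb1_at	FX16412	integrin beta 1 (fibronectin receptor beta)	16412	Itgb1	173	P
itgb2_at	FX16414	integrin beta 2	16414	Itgb2	484	P
itgb7_at	FX16421	integrin beta 7	16421	Itgb7	453	P
osm_at	FX18413	oncostatin M	18413	Osm	178	P
tnf_at	FX21926	tumor necrosis factor	21926	Tnf	102	P
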