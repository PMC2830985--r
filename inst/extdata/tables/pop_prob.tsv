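probe_set	accession	description	gene	symbol	intensity_1	call_1
acvr2a_at	FX11480	activin receptor IIA	11480	Acvr2a	139	P
acvr2b_at	FX11481	activin receptor IIB	11481	Acvr2b	178	P
ccr2_at	FX12772	chemokine (C-C motif) receptor 2	12772	Ccr2	141	P
ccr9_at	FX12769	chemokine (C-C motif) receptor 9	12769	Ccr9	376	P
cd28_at	FX12487	CD28 antigen	12487	Cd28	439	P
cxcr4_at	FX12767	chemokine (C-X-C motif) receptor 4	12767	Cxcr4	702	P
egfr_at	FX13649	epidermal growth factor receptor	13649	Egfr	193	P
igf2_at	FX16002	insulin-like growth factor 2	16002	Igf2	113	P
il2rg_at	FX16186	interleukin 2 receptor, gamma chain	16186	Il2rg	3348	P
itga4_at	FX16401	Integrin alpha 4	16401	Itga4	413	P
itgb1_at	FX16412	integrin beta 1 (fibronectin receptor beta)	16412	Itgb1	130	P
itgb2_at	FX16414	integrin beta 2	16414	Itgb2	4429	P
itgb7_at	FX16421	integrin beta 7	16421	Itgb7	2879	P
kdr_at	FX16542	kinase insert domain protein receptor	16542	Kdr	389	P
l1cam_at	FX16728	L1 cell adhesion molecule	16728	L1cam	596	P
nrp1_at	FX18186	neuropilin 1	18186	Nrp1	333	P
osm_at	FX18413	oncostatin M	18413	Osm	143	P
pdgfb_at	FX18591	platelet derived growth factor, B polypeptide	18591	Pdgfb	122	P
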