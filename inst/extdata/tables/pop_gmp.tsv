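probe_set	accession	description	gene	symbol	intensity_1	call_1
cxcr4_at	FX12767	chemokine (C-X-C motif) receptor 4	12767	Cxcr4	768	P
egfr_at	FX13649	epidermal growth factor receptor	13649	Egfr	182	P
il2rg_at	FX16186	interleukin 2 receptor, gamma chain	16186	Il2rg	869	P
itga4_at	FX16401	Integrin alpha 4	16401	Itga4	171	P
itgb1_at	FX16412	integrin beta 1 (fibronectin receptor beta)	16412	Itgb1	122	P
itgb2_at	FX16414	integrin beta 2	16414	Itgb2	969	P
nrp1_at	FX18186	neuropilin 1	18186	Nrp1	120	P
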