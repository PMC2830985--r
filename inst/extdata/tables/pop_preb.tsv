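probe_set	accession	description	gene	symbol	intensity_1	call_1
cxcr4_at	FX12767	chemokine (C-X-C motif) receptor 4	12767	Cxcr4	1526	P
egfr_at	FX13649	epidermal growth factor receptor	13649	Egfr	177	P
il2rg_at	FX16186	interleukin 2 receptor, gamma chain	16186	Il2rg	2147	P
itga4_at	FX16401	Integrin alpha 4	16401	Itga4	199	P
itgb2_at	FX16414	integrin beta 2	16414	Itgb2	1438	P
osm_at	FX18413	oncostatin M	18413	Osm	101	P
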