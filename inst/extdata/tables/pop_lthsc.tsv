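probe_set	accession	description	gene	symbol	intensity_1	call_1
acvr2b_at	FX11481	activin receptor IIB	11481	Acvr2b	267	P
bmp4_at	FX12159	bone morphogenetic protein 4	12159	Bmp4	169	P
cxcr4_at	FX12767	chemokine (C-X-C motif) receptor 4	12767	Cxcr4	372	P
egfr_at	FX13649	epidermal growth factor receptor	13649	Egfr	149	P
igf2_at	FX16002	insulin-like growth factor 2	16002	Igf2	105	P
itga4_at	FX16401	Integrin alpha 4	16401	Itga4	1675	P
itgb1_at	FX16412	integrin beta 1 (fibronectin receptor beta)	16412	Itgb1	307	P
itgb2_at	FX16414	integrin beta 2	16414	Itgb2	558	P
itgb7_at	FX16421	integrin beta 7	16421	Itgb7	329	P
jag2_at	FX16450	jagged 2	16450	Jag2	222	P
kdr_at	FX16542	kinase insert domain protein receptor	16542	Kdr	311	P
osm_at	FX18413	oncostatin M	18413	Osm	115	P
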