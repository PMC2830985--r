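# population: GMP
# stroma: OP9
pop_gene	pop_symbol	pop_intensity	stroma_gene	stroma_symbol	stroma_intensity	direction	autocrine	NIH3T3	MC3T3
12767	Cxcr4	768	20315	Cxcl12	12222	pop_receptor__stroma_ligand	FALSE	23	798
13649	Egfr	182	13874	Ereg	422	pop_receptor__stroma_ligand	FALSE	288	153
16186	Il2rg	869	16196	Il7	189	pop_receptor__stroma_ligand	FALSE	92	255
16401	Itga4	171	67374	Jam2	201	adhesion_pair	FALSE	16	26
16412	Itgb1	122	67374	Jam2	201	adhesion_pair	FALSE	16	26
16414	Itgb2	969	83964	Jam3	152	adhesion_pair	FALSE	42	204
13649	Egfr	182	21802	Tgfa	261	pop_receptor__stroma_ligand	FALSE	13	21
16401	Itga4	171	22329	Vcam1	692	adhesion_pair	FALSE	182	929
16412	Itgb1	122	22329	Vcam1	692	adhesion_pair	FALSE	182	929
18186	Nrp1	120	22339	Vegfa	179	pop_receptor__stroma_ligand	FALSE	1006	169
18186	Nrp1	120	22340	Vegfb	174	pop_receptor__stroma_ligand	FALSE	191	639
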