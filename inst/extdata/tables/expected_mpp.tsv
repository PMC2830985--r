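# population: MPP
# stroma: OP9
pop_gene	pop_symbol	pop_intensity	stroma_gene	stroma_symbol	stroma_intensity	direction	autocrine	NIH3T3	MC3T3
11481	Acvr2b	183	12159	Bmp4	1335	pop_receptor__stroma_ligand	FALSE	66	252
12155	Bmp15	413	12166	Bmpr1a	327	pop_ligand__stroma_receptor	FALSE	377	287
12159	Bmp4	112	12166	Bmpr1a	327	pop_ligand__stroma_receptor	FALSE	377	287
12767	Cxcr4	264	20315	Cxcl12	12222	pop_receptor__stroma_ligand	FALSE	23	798
13649	Egfr	231	13874	Ereg	422	pop_receptor__stroma_ligand	FALSE	288	153
16002	Igf2	271	16004	Igf2r	535	pop_ligand__stroma_receptor	FALSE	1772	1704
16177	Il1r1	123	16181	Il1rn	3515	pop_receptor__stroma_ligand	FALSE	16	10
16401	Itga4	278	67374	Jam2	201	adhesion_pair	FALSE	16	26
16412	Itgb1	180	67374	Jam2	201	adhesion_pair	FALSE	16	26
16414	Itgb2	507	83964	Jam3	152	adhesion_pair	FALSE	42	204
18413	Osm	157	18414	Osmr	1151	pop_ligand__stroma_receptor	FALSE	1349	131
13649	Egfr	231	21802	Tgfa	261	pop_receptor__stroma_ligand	FALSE	13	21
16401	Itga4	278	22329	Vcam1	692	adhesion_pair	FALSE	182	929
16412	Itgb1	180	22329	Vcam1	692	adhesion_pair	FALSE	182	929
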