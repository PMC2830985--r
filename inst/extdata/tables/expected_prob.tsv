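# population: proB
# stroma: OP9
pop_gene	pop_symbol	pop_intensity	stroma_gene	stroma_symbol	stroma_intensity	direction	autocrine	NIH3T3	MC3T3
11480	Acvr2a	139	12159	Bmp4	1335	pop_receptor__stroma_ligand	FALSE	66	252
11481	Acvr2b	178	12159	Bmp4	1335	pop_receptor__stroma_ligand	FALSE	66	252
12772	Ccr2	141	20296	Ccl2	239	pop_receptor__stroma_ligand	FALSE	3362	362
12769	Ccr9	376	20300	Ccl25	123	pop_receptor__stroma_ligand	FALSE	55	100
12487	Cd28	439	12519	Cd80	462	pop_receptor__stroma_ligand	FALSE	38	71
12767	Cxcr4	702	20315	Cxcl12	12222	pop_receptor__stroma_ligand	FALSE	23	798
13649	Egfr	193	13874	Ereg	422	pop_receptor__stroma_ligand	FALSE	288	153
16002	Igf2	113	16004	Igf2r	535	pop_ligand__stroma_receptor	FALSE	1772	1704
16186	Il2rg	3348	16196	Il7	189	pop_receptor__stroma_ligand	FALSE	92	255
16401	Itga4	413	67374	Jam2	201	adhesion_pair	FALSE	16	26
16412	Itgb1	130	67374	Jam2	201	adhesion_pair	FALSE	16	26
16414	Itgb2	4429	83964	Jam3	152	adhesion_pair	FALSE	42	204
16728	L1cam	596	17967	Ncam1	129	adhesion_pair	FALSE	740	545
18413	Osm	143	18414	Osmr	1151	pop_ligand__stroma_receptor	FALSE	1349	131
18591	Pdgfb	122	18595	Pdgfra	2140	pop_ligand__stroma_receptor	FALSE	1066	445
18591	Pdgfb	122	18596	Pdgfrb	1829	pop_ligand__stroma_receptor	FALSE	505	1782
13649	Egfr	193	21802	Tgfa	261	pop_receptor__stroma_ligand	FALSE	13	21
16401	Itga4	413	22329	Vcam1	692	adhesion_pair	FALSE	182	929
16412	Itgb1	130	22329	Vcam1	692	adhesion_pair	FALSE	182	929
16421	Itgb7	2879	22329	Vcam1	692	adhesion_pair	FALSE	182	929
16542	Kdr	389	22339	Vegfa	275	pop_receptor__stroma_ligand	FALSE	1872	387
18186	Nrp1	333	22339	Vegfa	275	pop_receptor__stroma_ligand	FALSE	1872	387
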