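# population: CLP
# stroma: OP9
pop_gene	pop_symbol	pop_intensity	stroma_gene	stroma_symbol	stroma_intensity	direction	autocrine	NIH3T3	MC3T3
11481	Acvr2b	166	12159	Bmp4	1335	pop_receptor__stroma_ligand	FALSE	66	252
12155	Bmp15	645	12166	Bmpr1a	497	pop_ligand__stroma_receptor	FALSE	274	384
12769	Ccr9	443	20300	Ccl25	123	pop_receptor__stroma_ligand	FALSE	55	100
12767	Cxcr4	2121	20315	Cxcl12	12222	pop_receptor__stroma_ligand	FALSE	23	798
13649	Egfr	193	13874	Ereg	422	pop_receptor__stroma_ligand	FALSE	288	153
16002	Igf2	282	16004	Igf2r	535	pop_ligand__stroma_receptor	FALSE	1772	1704
16177	Il1r1	180	16181	Il1rn	3515	pop_receptor__stroma_ligand	FALSE	16	10
16178	Il1r2	127	16181	Il1rn	3515	pop_receptor__stroma_ligand	FALSE	16	10
16186	Il2rg	3021	16196	Il7	189	pop_receptor__stroma_ligand	FALSE	92	255
16401	Itga4	1982	67374	Jam2	201	adhesion_pair	FALSE	16	26
16414	Itgb2	920	83964	Jam3	152	adhesion_pair	FALSE	42	204
18413	Osm	112	18414	Osmr	1151	pop_ligand__stroma_receptor	FALSE	1349	131
13649	Egfr	193	21802	Tgfa	261	pop_receptor__stroma_ligand	FALSE	13	21
16401	Itga4	1982	22329	Vcam1	692	adhesion_pair	FALSE	182	929
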