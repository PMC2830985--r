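# population: LT-HSC
# stroma: OP9
pop_gene	pop_symbol	pop_intensity	stroma_gene	stroma_symbol	stroma_intensity	direction	autocrine	NIH3T3	MC3T3
11481	Acvr2b	267	12159	Bmp4	1335	pop_receptor__stroma_ligand	FALSE	66	252
12159	Bmp4	169	12166	Bmpr1a	497	pop_ligand__stroma_receptor	FALSE	274	384
12767	Cxcr4	372	20315	Cxcl12	12222	pop_receptor__stroma_ligand	FALSE	23	798
13649	Egfr	149	13874	Ereg	422	pop_receptor__stroma_ligand	FALSE	288	153
16002	Igf2	105	16004	Igf2r	535	pop_ligand__stroma_receptor	FALSE	1772	1704
16401	Itga4	1675	67374	Jam2	201	adhesion_pair	FALSE	16	26
16412	Itgb1	307	67374	Jam2	201	adhesion_pair	FALSE	16	26
16414	Itgb2	558	83964	Jam3	152	adhesion_pair	FALSE	42	204
16450	Jag2	222	18131	Notch3	367	pop_ligand__stroma_receptor	FALSE	161	48
18413	Osm	115	18414	Osmr	1151	pop_ligand__stroma_receptor	FALSE	1349	131
13649	Egfr	149	21802	Tgfa	261	pop_receptor__stroma_ligand	FALSE	13	21
16401	Itga4	1675	22329	Vcam1	692	adhesion_pair	FALSE	182	929
16412	Itgb1	307	22329	Vcam1	692	adhesion_pair	FALSE	182	929
16421	Itgb7	329	22329	Vcam1	692	adhesion_pair	FALSE	182	929
16542	Kdr	311	22339	Vegfa	179	pop_receptor__stroma_ligand	FALSE	1006	169
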