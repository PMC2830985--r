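# population: LMPP
# stroma: OP9
pop_gene	pop_symbol	pop_intensity	stroma_gene	stroma_symbol	stroma_intensity	direction	autocrine	NIH3T3	MC3T3
11477	Acvr1	107	12159	Bmp4	1335	pop_receptor__stroma_ligand	FALSE	66	252
11480	Acvr2a	131	12159	Bmp4	1335	pop_receptor__stroma_ligand	FALSE	66	252
12159	Bmp4	277	12166	Bmpr1a	497	pop_ligand__stroma_receptor	FALSE	274	384
12767	Cxcr4	290	20315	Cxcl12	12222	pop_receptor__stroma_ligand	FALSE	23	798
13649	Egfr	189	13874	Ereg	422	pop_receptor__stroma_ligand	FALSE	288	153
16002	Igf2	139	16004	Igf2r	535	pop_ligand__stroma_receptor	FALSE	1772	1704
16186	Il2rg	2115	16196	Il7	189	pop_receptor__stroma_ligand	FALSE	92	255
16401	Itga4	268	67374	Jam2	201	adhesion_pair	FALSE	16	26
16412	Itgb1	173	67374	Jam2	201	adhesion_pair	FALSE	16	26
16414	Itgb2	484	83964	Jam3	152	adhesion_pair	FALSE	42	204
18413	Osm	178	18414	Osmr	1151	pop_ligand__stroma_receptor	FALSE	1349	131
13649	Egfr	189	21802	Tgfa	261	pop_receptor__stroma_ligand	FALSE	13	21
21926	Tnf	102	21937	Tnfrsf1a	1974	pop_ligand__stroma_receptor	FALSE	959	1143
21926	Tnf	102	21938	Tnfrsf1b	108	pop_ligand__stroma_receptor	FALSE	721	108
16401	Itga4	268	22329	Vcam1	692	adhesion_pair	FALSE	182	929
16412	Itgb1	173	22329	Vcam1	692	adhesion_pair	FALSE	182	929
16421	Itgb7	453	22329	Vcam1	692	adhesion_pair	FALSE	182	929
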