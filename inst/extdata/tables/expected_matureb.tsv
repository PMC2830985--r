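# population: matureB
# stroma: OP9
pop_gene	pop_symbol	pop_intensity	stroma_gene	stroma_symbol	stroma_intensity	direction	autocrine	NIH3T3	MC3T3
12767	Cxcr4	1275	20315	Cxcl12	12222	pop_receptor__stroma_ligand	FALSE	23	798
13649	Egfr	145	13874	Ereg	422	pop_receptor__stroma_ligand	FALSE	288	153
16186	Il2rg	2746	16196	Il7	189	pop_receptor__stroma_ligand	FALSE	92	255
16401	Itga4	1640	67374	Jam2	201	adhesion_pair	FALSE	16	26
16412	Itgb1	235	67374	Jam2	201	adhesion_pair	FALSE	16	26
16414	Itgb2	1781	83964	Jam3	152	adhesion_pair	FALSE	42	204
16992	Lta	540	17000	Ltbr	965	pop_ligand__stroma_receptor	FALSE	285	519
21803	Tgfb1	718	70458	Odc-rs	197	adhesion_pair	FALSE	146	14
13649	Egfr	145	21802	Tgfa	261	pop_receptor__stroma_ligand	FALSE	13	21
21803	Tgfb1	718	21813	Tgfbr2	171	pop_ligand__stroma_receptor	FALSE	85	253
21803	Tgfb1	718	21814	Tgfbr3	3653	pop_ligand__stroma_receptor	FALSE	3429	1152
16992	Lta	540	21937	Tnfrsf1a	1974	pop_ligand__stroma_receptor	FALSE	959	1143
16992	Lta	540	21938	Tnfrsf1b	108	pop_ligand__stroma_receptor	FALSE	721	108
16401	Itga4	1640	22329	Vcam1	692	adhesion_pair	FALSE	182	929
16412	Itgb1	235	22329	Vcam1	692	adhesion_pair	FALSE	182	929
16421	Itgb7	942	22329	Vcam1	692	adhesion_pair	FALSE	182	929
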