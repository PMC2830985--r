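pair_id	gene_a	symbol_a	role_a	gene_b	symbol_b	role_b	source
P001	11481	Acvr2b	receptor	12159	Bmp4	ligand	transcribed interaction tables
P002	12159	Bmp4	ligand	12166	Bmpr1a	receptor	transcribed interaction tables
P003	12767	Cxcr4	receptor	20315	Cxcl12	ligand	transcribed interaction tables
P004	13649	Egfr	receptor	13874	Ereg	ligand	transcribed interaction tables
P005	16002	Igf2	ligand	16004	Igf2r	receptor	transcribed interaction tables
P006	16401	Itga4	adhesion	67374	Jam2	adhesion	transcribed interaction tables
P007	16412	Itgb1	adhesion	67374	Jam2	adhesion	transcribed interaction tables
P008	16414	Itgb2	adhesion	83964	Jam3	adhesion	transcribed interaction tables
P009	16450	Jag2	ligand	18131	Notch3	receptor	transcribed interaction tables
P010	18413	Osm	ligand	18414	Osmr	receptor	transcribed interaction tables
P011	13649	Egfr	receptor	21802	Tgfa	ligand	transcribed interaction tables
P012	16401	Itga4	adhesion	22329	Vcam1	adhesion	transcribed interaction tables
P013	16412	Itgb1	adhesion	22329	Vcam1	adhesion	transcribed interaction tables
P014	16421	Itgb7	adhesion	22329	Vcam1	adhesion	transcribed interaction tables
P015	16542	Kdr	receptor	22339	Vegfa	ligand	transcribed interaction tables
P016	12155	Bmp15	ligand	12166	Bmpr1a	receptor	transcribed interaction tables
P017	16177	Il1r1	receptor	16181	Il1rn	ligand	transcribed interaction tables
P018	11480	Acvr2a	receptor	12159	Bmp4	ligand	transcribed interaction tables
P019	11477	Acvr1	receptor	12159	Bmp4	ligand	transcribed interaction tables
P020	16186	Il2rg	receptor	16196	Il7	ligand	transcribed interaction tables
P021	21926	Tnf	ligand	21937	Tnfrsf1a	receptor	transcribed interaction tables
P022	21926	Tnf	ligand	21938	Tnfrsf1b	receptor	transcribed interaction tables
P023	12769	Ccr9	receptor	20300	Ccl25	ligand	transcribed interaction tables
P024	16178	Il1r2	receptor	16181	Il1rn	ligand	transcribed interaction tables
P025	18186	Nrp1	receptor	22339	Vegfa	ligand	transcribed interaction tables
P026	18186	Nrp1	receptor	22340	Vegfb	ligand	transcribed interaction tables
P027	12487	Cd28	receptor	12519	Cd80	ligand	transcribed interaction tables
P028	16728	L1cam	adhesion	17967	Ncam1	adhesion	transcribed interaction tables
P029	18591	Pdgfb	ligand	18595	Pdgfra	receptor	transcribed interaction tables
P030	18591	Pdgfb	ligand	18596	Pdgfrb	receptor	transcribed interaction tables
P031	12772	Ccr2	receptor	20296	Ccl2	ligand	transcribed interaction tables
P032	16992	Lta	ligand	17000	Ltbr	receptor	transcribed interaction tables
P033	21803	Tgfb1	ligand	70458	Odc-rs	unknown	transcribed interaction tables
P034	21803	Tgfb1	ligand	21813	Tgfbr2	receptor	transcribed interaction tables
P035	21803	Tgfb1	ligand	21814	Tgfbr3	receptor	transcribed interaction tables
P036	16992	Lta	ligand	21937	Tnfrsf1a	receptor	transcribed interaction tables
P037	16992	Lta	ligand	21938	Tnfrsf1b	receptor	transcribed interaction tables
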