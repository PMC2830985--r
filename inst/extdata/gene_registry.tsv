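gene	symbol	role	description
11477	Acvr1	receptor	activin A receptor, type 1
11480	Acvr2a	receptor	activin receptor IIA
11481	Acvr2b	receptor	activin receptor IIB
12155	Bmp15	ligand	Bone morphogenetic protein 15
12159	Bmp4	ligand	bone morphogenetic protein 4
12166	Bmpr1a	receptor	bone morphogenetic protein receptor, type 1A
20296	Ccl2	ligand	chemokine (C-C motif) ligand 2
20300	Ccl25	ligand	chemokine (C-C motif) ligand 25
12772	Ccr2	receptor	chemokine (C-C motif) receptor 2
12769	Ccr9	receptor	chemokine (C-C motif) receptor 9
12487	Cd28	receptor	CD28 antigen
12519	Cd80	ligand	CD80 antigen
20315	Cxcl12	ligand	chemokine (C-X-C motif) ligand 12
12767	Cxcr4	receptor	chemokine (C-X-C motif) receptor 4
13649	Egfr	receptor	epidermal growth factor receptor
13874	Ereg	ligand	epiregulin
16002	Igf2	ligand	insulin-like growth factor 2
16004	Igf2r	receptor	insulin-like growth factor 2 receptor
16177	Il1r1	receptor	interleukin 1 receptor, type I
16178	Il1r2	receptor	interleukin 1 receptor, type II
16181	Il1rn	ligand	interleukin 1 receptor antagonist
16186	Il2rg	receptor	interleukin 2 receptor, gamma chain
16196	Il7	ligand	interleukin 7
16401	Itga4	adhesion	Integrin alpha 4
16412	Itgb1	adhesion	integrin beta 1 (fibronectin receptor beta)
16414	Itgb2	adhesion	integrin beta 2
16421	Itgb7	adhesion	integrin beta 7
16450	Jag2	ligand	jagged 2
67374	Jam2	adhesion	junction adhesion molecule 2
83964	Jam3	adhesion	junction adhesion molecule 3
16542	Kdr	receptor	kinase insert domain protein receptor
16728	L1cam	adhesion	L1 cell adhesion molecule
16992	Lta	ligand	lymphotoxin A
17000	Ltbr	receptor	lymphotoxin B receptor
17967	Ncam1	adhesion	neural cell adhesion molecule 1
18131	Notch3	receptor	Notch gene homolog 3 (Drosophila)
18186	Nrp1	receptor	neuropilin 1
70458	Odc-rs	unknown	Similar to Ornithine decarboxylase (ODC)
18413	Osm	ligand	oncostatin M
18414	Osmr	receptor	oncostatin M receptor
18591	Pdgfb	ligand	platelet derived growth factor, B polypeptide
18595	Pdgfra	receptor	platelet derived growth factor receptor, alpha polypeptide
18596	Pdgfrb	receptor	platelet derived growth factor receptor, beta polypeptide
21802	Tgfa	ligand	transforming growth factor alpha
21803	Tgfb1	ligand	transforming growth factor, beta 1
21813	Tgfbr2	receptor	transforming growth factor, beta receptor II
21814	Tgfbr3	receptor	transforming growth factor, beta receptor III
21926	Tnf	ligand	tumor necrosis factor
21937	Tnfrsf1a	receptor	tumor necrosis factor receptor superfamily, member 1a
21938	Tnfrsf1b	receptor	tumor necrosis factor receptor superfamily, member 1b
22329	Vcam1	adhesion	vascular cell adhesion molecule 1
22339	Vegfa	ligand	vascular endothelial growth factor A
22340	Vegfb	ligand	vascular endothelial growth factor B
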