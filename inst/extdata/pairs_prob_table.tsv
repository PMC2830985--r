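pair_id	gene_a	symbol_a	role_a	gene_b	symbol_b	role_b	source
T6-01	11480	Acvr2a	receptor	12159	Bmp4	ligand	transcribed pro-B interaction table
T6-02	11481	Acvr2b	receptor	12159	Bmp4	ligand	transcribed pro-B interaction table
T6-03	12487	Cd28	receptor	12519	Cd80	ligand	transcribed pro-B interaction table
T6-04	13649	Egfr	receptor	13874	Ereg	ligand	transcribed pro-B interaction table
T6-05	16002	Igf2	ligand	16004	Igf2r	receptor	transcribed pro-B interaction table
T6-06	16186	Il2rg	receptor	16196	Il7	ligand	transcribed pro-B interaction table
T6-07	16728	L1cam	adhesion	17967	Ncam1	adhesion	transcribed pro-B interaction table
T6-08	18413	Osm	ligand	18414	Osmr	receptor	transcribed pro-B interaction table
T6-09	18591	Pdgfb	ligand	18595	Pdgfra	receptor	transcribed pro-B interaction table
T6-10	18591	Pdgfb	ligand	18596	Pdgfrb	receptor	transcribed pro-B interaction table
T6-11	12772	Ccr2	receptor	20296	Ccl2	ligand	transcribed pro-B interaction table
T6-12	12769	Ccr9	receptor	20300	Ccl25	ligand	transcribed pro-B interaction table
T6-13	12767	Cxcr4	receptor	20315	Cxcl12	ligand	transcribed pro-B interaction table
T6-14	13649	Egfr	receptor	21802	Tgfa	ligand	transcribed pro-B interaction table
T6-15	16401	Itga4	adhesion	22329	Vcam1	adhesion	transcribed pro-B interaction table
T6-16	16421	Itgb7	adhesion	22329	Vcam1	adhesion	transcribed pro-B interaction table
T6-17	16412	Itgb1	adhesion	22329	Vcam1	adhesion	transcribed pro-B interaction table
T6-18	18186	Nrp1	receptor	22339	Vegfa	ligand	transcribed pro-B interaction table
T6-19	16542	Kdr	receptor	22339	Vegfa	ligand	transcribed pro-B interaction table
T6-20	16412	Itgb1	adhesion	67374	Jam2	adhesion	transcribed pro-B interaction table
T6-21	16401	Itga4	adhesion	67374	Jam2	adhesion	transcribed pro-B interaction table
T6-22	16414	Itgb2	adhesion	83964	Jam3	adhesion	transcribed pro-B interaction table
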