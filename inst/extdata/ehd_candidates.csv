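# Screening candidate list: 19 Erhuang decoction constituents plus dexamethasone (control).
# Curated structures for these natural products are not bundled with the package.
# 'smiles' is intentionally empty for the user to fill with curated structures.
# 'synthetic_smiles' are SYNTHETIC stand-in structures (valid drug-like molecules,
# NOT the real natural products) used by package examples and tests.
id,name,smiles,synthetic_smiles
1,Neoglycyrol,,COc1ccc2oc(=O)ccc2c1O
2,Uralenol,,Oc1cc(O)c2c(=O)c(O)c(-c3ccc(O)c(O)c3)oc2c1
3,Syringic acid 4-beta-D-glucopyranoside,,COc1cc(C(=O)O)cc(OC)c1OC1OC(CO)C(O)C(O)C1O
4,Gancaonin N,,CC(C)=CCc1c(O)cc2occ(-c3ccc(O)cc3)c(=O)c2c1O
5,Chrysin-6-C-glucoside-8-C-arabinoside,,OCC1OC(c2c(O)cc3oc(-c4ccccc4)cc(=O)c3c2O)C(O)C(O)C1O
6,Chrysin-6-C-arabinoside-8-C-glucoside,,OC1COC(c2c(O)cc3oc(-c4ccccc4)cc(=O)c3c2O)C(O)C1O
7,Liquiritin,,Oc1ccc(C2CC(=O)c3ccc(OC4OC(CO)C(O)C(O)C4O)cc3O2)cc1
8,Baicalin,,O=C(O)C1OC(Oc2cc3oc(-c4ccccc4)cc(=O)c3c(O)c2O)C(O)C(O)C1O
9,Isomer of Baicalin,,O=C(O)C1OC(Oc2c(O)cc3oc(-c4ccccc4)cc(=O)c3c2O)C(O)C(O)C1O
10,Oroxylin A-7-O-beta-D-glucuronide,,COc1c(O)c2c(=O)cc(-c3ccccc3)oc2cc1OC1OC(C(=O)O)C(O)C(O)C1O
11,Chrysin-7-O-glucuronide,,O=C(O)C1OC(Oc2cc3oc(-c4ccccc4)cc(=O)c3c(O)c2)C(O)C(O)C1O
12,Isoliquiritin,,Oc1ccc(/C=C/C(=O)c2ccc(OC3OC(CO)C(O)C(O)C3O)cc2O)cc1
13,Wogonoside,,COc1c(OC2OC(C(=O)O)C(O)C(O)C2O)cc2oc(-c3ccccc3)cc(=O)c2c1O
14,Liquiritigenin,,Oc1ccc(C2CC(=O)c3ccc(O)cc3O2)cc1
15,Baicalein,,Oc1cc2oc(-c3ccccc3)cc(=O)c2c(O)c1O
16,Isoliquiritigenin,,Oc1ccc(/C=C/C(=O)c2ccc(O)cc2O)cc1
17,Wogonin,,COc1c(O)cc2oc(-c3ccccc3)cc(=O)c2c1O
18,Oroxylin A,,COc1cc2oc(-c3ccccc3)cc(=O)c2c(O)c1O
19,Glycyrrhetinic acid,,CC1(C)CCC2(CCC3(C)C(=CC(=O)C4C5(C)CCC(O)C(C)(C)C5CCC34C)C2C1)C(=O)O
20,DXMS,,CC1CC2C3CCC(=O)C=C3CCC2C2(C)CCC(O)(C(=O)CO)C12C
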