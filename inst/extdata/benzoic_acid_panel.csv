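"name","smiles","pka_ref"
"Benzoic Acid","OC(=O)c1ccccc1",4.2
"4-Cyanobenzoic Acid","N#Cc1ccc(cc1)C(=O)O",3.55
"2,6-Dimethylbenzoic Acid","OC(=O)c1c(C)cccc1C",3.24
"4-Bromobenzoic Acid","OC(=O)c1ccc(cc1)Br",3.96
"2-Bromobenzoic Acid","OC(=O)c1ccccc1Br",2.96
"2-Chlorobenzoic Acid","OC(=O)c1ccccc1Cl",2.96
"3-Chlorobenzoic Acid","Clc1cccc(c1)C(=O)O",3.83
"4-Chlorobenzoic Acid","OC(=O)c1ccc(cc1)Cl",3.99
"2-Methoxybenzoic Acid","COc1ccccc1C(=O)O",4.09
"3-Methoxybenzoic Acid","COc1cccc(c1)C(=O)O",4.1
"4-Methoxybenzoic Acid","COc1ccc(cc1)C(=O)O",4.5
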