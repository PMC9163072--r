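id	roles	synonym
L1	ligand	ligand 1
L2	ligand	ligand 2
R1	receptor	receptor 1
R2	receptor	receptor 2
S1	signaling	kinase 1
S2	signaling	kinase 2
T1	TF	factor 1
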