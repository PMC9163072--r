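source	target	moa	reversible	references	pubmed
L1	R1	stimulation	0	demo	
L2	R2	stimulation	0	demo	
R1	S1	stimulation	0	demo;curated	123456
R2	S2	stimulation	0	demo	
S1	T1	stimulation	0	demo	
S2	T1	inhibition	0	demo	
S1	S2	stimulation	0	demo	
T1	S1	inhibition	0	demo	
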