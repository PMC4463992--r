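parameter	description	weight
q1	protein density (radial-shell spatial structure)	0.3183
q2	total number of atoms	0.0343
q3	number of amino acids	0.0204
q4	amino acid types	0.0603
q5	C proportion	0.0653
q6	N proportion	0.1062
q7	O proportion	0.1002
q8	P position	0.1477
q9	S position	0.1480
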