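node	score
S100A11	0.8102
RASEF	0.8068
GCN4	0.7624
FKBP	0.7334
CENP-B	0.7312
S100A2	0.7046
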