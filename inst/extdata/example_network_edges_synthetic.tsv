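source	target	sign
S100A11	RAGE	+
RAGE	P38	+
P38	MAPK	+
MAPK	Microtubule-associated protein	+
Microtubule-associated protein	Spindle protein	+
Spindle protein	Centromere protein	+
Centromere protein	Cell proliferation	+
RASEF	Ras	+
Ras	Raf-1	+
Raf-1	MEK	+
MEK	MAPK kinase	+
MAPK kinase	MAPK	+
GCN4	Transcription activation	+
Transcription activation	Cell proliferation	+
FKBP	P38	-
CENP-B	Centromere protein	+
S100A2	Cell proliferation	-
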