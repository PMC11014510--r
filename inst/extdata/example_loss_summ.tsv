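GENE	MLKL	L
TRANSCRIPT	ENST00000306874	I
GENE	RIPK3	L
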