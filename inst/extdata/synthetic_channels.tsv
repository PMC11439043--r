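pathway	chain	resno	frame
H	A	38	template
H	A	51	template
H	A	371	template
H	A	407	template
H	A	413	template
H	A	440	template
H	A	441	template
K	A	255	template
K	A	316	template
K	A	319	template
K	A	354	template
K	A	362	template
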