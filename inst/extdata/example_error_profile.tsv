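position	ref_base	alt_base	probability
*	*	*	0.001
0	A	G	0.01
1	A	G	0.01
*	C	T	0.002
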