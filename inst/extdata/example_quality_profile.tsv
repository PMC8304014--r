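position	base	mean_q	sd_q	is_error
*	*	37	2	0
*	*	25	5	1
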