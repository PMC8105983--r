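ref_pos	expected	region
25	R	synthase_core
29	F	synthase_core
35	W	synthase_core
44	E	synthase_core
49	D	synthase_core
70	R	synthase_core
104	R	synthase_core
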