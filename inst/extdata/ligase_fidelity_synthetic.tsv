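base_a	base_b	weight
A	A	0.05
A	C	0.05
A	G	0.05
A	T	1
C	A	0.05
C	C	0.05
C	G	1
C	T	0.05
G	A	0.05
G	C	1
G	G	0.05
G	T	0.3
T	A	1
T	C	0.05
T	G	0.3
T	T	0.05
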