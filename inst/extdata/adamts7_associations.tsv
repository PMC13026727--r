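trait	beta	se	p	q
AST	1.56	0.80	0.05	1
ALT	4.24	1.21	4.9e-4	0.35
AST/ALT	-0.05	0.02	5.2e-3	0.99
CAP	7.66	3.64	3.0e-2	0.81
FAST	1.56	0.80	1	1
BDI-II	-0.73	0.24	2.3e-3	0.10
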