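trait	beta	se	p	q
AST	-1.53	0.80	5.6e-2	1
ALT	-4.06	1.21	8.8e-4	0.35
AST/ALT	0.05	0.02	9.1e-3	0.99
CAP	-8.13	3.52	2.2e-2	0.77
FAST	-0.01	0.01	5.6e-2	0.21
BDI-II	0.04	0.24	1.4e-1	NA
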