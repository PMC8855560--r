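x1	x2	x3	rhodiff	mla_value	wald	p	bonferroni
PELI2	FHL5	NQO1	1.0672	0.3849	30.5523	3.25E-08	9.75E-03
CNKSR1	NSUN6	AOX1	1.1351	0.4016	29.7896	4.82E-08	1.45E-02
PELI2	FHL5	AOX1	-1.2243	-0.4384	28.9932	7.26E-08	2.18E-02
PELI2	FHL5	TSPAN1	1.1780	0.4130	28.4857	9.44E-08	2.83E-02
EPHX1	GUCY1A3	TSPAN1	1.1812	0.4154	28.3721	1.00E-07	3.00E-02
PELI2	SVEP1	AOX1	-1.2403	-0.4400	27.9954	1.22E-07	3.66E-02
MAN1A2	SLC9A9	CXCL12	-1.1935	-0.4272	27.5945	1.50E-07	4.50E-02
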