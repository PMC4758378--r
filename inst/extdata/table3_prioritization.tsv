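gene	upre	erse1	erse2	interaction_type	rho	fdr_cor
RAB5A	+	+		Indirect	0.48	0.0038
HMGB1	+	+		Indirect	0.39	0.026
CTNNB1		+		Direct	0.82	0
DNM1	+	+		Direct	0.55	0.00050
TCP1	+	+		Indirect	0.62	0.00014
TUBB	+	+		Indirect	0.60	0.00025
TSG101	+	+		Indirect	0.73	0
DNAJB1	+		+	Indirect	-0.22	1
CCT2				Indirect	0.79	0
EEF2				Indirect	0.81	0
DYNC1H1				Indirect	0.57	0.00038
HSPA5				Indirect	0.07	0.81
SLC12A5				Indirect	-0.06	1
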