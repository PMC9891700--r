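gene	reference
KLK3	2.8
KLK2	2.5
TMPRSS2	2.2
FKBP5	2.0
SLC45A3	1.9
NKX3-1	1.8
PMEPA1	1.7
STEAP4	1.6
ABCC4	1.5
ACSL3	1.4
EAF2	1.3
NDRG1	1.2
CAMKK2	1.1
ELL2	1.0
GNMT	0.95
ZBTB10	0.9
ADAM7	0.85
HERC3	0.8
PTGER4	0.75
PLPP1	0.7
C1ORF116	0.65
MED28	0.6
MAF	0.55
TPD52	0.5
ABHD2	0.45
PART1	0.4
CENPN	0.35
MPHOSPH9	0.3
OPRK1	-1.2
SERPINI1	-0.9
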