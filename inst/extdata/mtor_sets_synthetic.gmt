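MTOR_UP	synthetic mTORC1-activation up set	SLC7A5	SLC3A2	PSAT1	PHGDH	SHMT2	MTHFD2	ASNS	ATF4	HK2	LDHA	PKM	SREBF1	FASN	SCD	ACACA	CCND1	NCL	NOP56	UNG	CAD
MTOR_DOWN	synthetic mTORC1-activation down set (autophagy/lysosome program)	CTSD	CTSF	CTSB	NEU1	HEXA	LAMP1	MAP1LC3B	SQSTM1	ULK1	GABARAPL1	ATG3	ATG5	WIPI1	MCOLN1	TFEB	PPARGC1A	BNIP3	SESN2	DDIT4	ATG12
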