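# Gene symbol dictionary: canonical_id<TAB>surface_form.
# Covers the catalogue symbols plus common protein aliases.
ABCB1	ABCB1
AGER	AGER
AKT1	AKT1
ALPP	ALPP
ATM	ATM
BGLAP	BGLAP
CASP3	CASP3
CCNE1	CCNE1
CFTR	CFTR
COX2	COX2
CYP19A1	CYP19A1
CYP3A4	CYP3A4
DDIT3	DDIT3
DDIT4	DDIT4
ERBB2	ERBB2
FBP1	FBP1
FOXO3	FOXO3
G6PC	G6Pase
G6PC	G6PC
GAPDH	GAPDH
GLP1	GLP1
HIF1A	HIF1A
I2BR	I2BR
IGFBP1	IGFBP1
IL1RN	IL1RN
IL6	IL6
INS	INS
INSR	INSR
IRS2	IRS2
IRTK	IRTK
KAT2A	KAT2A
KLF15	KLF15
MAPK1	MAPK1
MAPK3	MAPK3
MAPK8	MAPK8
MEF2A	MEF2A
MET	MET
MTOR	MTOR
MYC	MYC
NFKB	NFKB
NR0B2	NR0B2
NR1I2	NR1I2
PCK1	PCK1
PCK2	PCK2
PIK3	PIK3
PKLR	PKLR
PPARA	PPARA
PPARGC1A	PPARGC1A
PPP2R4	PPP2R4
PRKAA2	AMPK
PRKAA2	PRKAA2
RAB4A	RAB4A
RPS6KB1	RPS6KB1
SEPP1	SEPP1
SERPINE1	SERPINE1
SHBG	SHBG
SIRT1	SIRT1
SLC22A1	OCT1
SLC22A1	SLC22A1
SLC22A2	OCT2
SLC22A2	SLC22A2
SLC22A3	OCT3
SLC22A3	SLC22A3
SLC29A4	PMAT
SLC29A4	SLC29A4
SLC2A2	SLC2A2
SLC2A4	GLUT4
SLC2A4	SLC2A4
SLC47A1	MATE1
SLC47A1	SLC47A1
SLC47A2	MATE2
SLC47A2	SLC47A2
SREBF1	SREBF1
STAT3	STAT3
STK11	LKB1
STK11	STK11
TIMP2	TIMP2
TNFA	TNFA
TP53	TP53
TSC1	TSC1
TSC2	TSC2
TXNIP	TXNIP
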