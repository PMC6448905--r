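# Synthetic transcription of the published evidence-ranked gene lists:
# each printed tier membership is backed by two minimal concordant
# records with synthetic article ids. Not the original curation data.
gene_id	article_id	study_category	finding	direction
SLC22A1	SYN0001	clinical_outcome	effect	increased
SLC22A1	SYN0002	clinical_outcome	effect	increased
SLC47A1	SYN0003	clinical_outcome	effect	increased
SLC47A1	SYN0004	clinical_outcome	effect	increased
STK11	SYN0005	clinical_outcome	effect	increased
STK11	SYN0006	clinical_outcome	effect	increased
ATM	SYN0007	clinical_outcome	effect	increased
ATM	SYN0008	clinical_outcome	effect	increased
PRKAA2	SYN0009	clinical_outcome	effect	increased
PRKAA2	SYN0010	clinical_outcome	effect	increased
SLC22A2	SYN0011	clinical_outcome	effect	increased
SLC22A2	SYN0012	clinical_outcome	effect	increased
SHBG	SYN0013	clinical_outcome	effect	increased
SHBG	SYN0014	clinical_outcome	effect	increased
SLC47A2	SYN0015	pk_pd	effect	increased
SLC47A2	SYN0016	pk_pd	effect	increased
SLC22A3	SYN0017	pk_pd	effect	increased
SLC22A3	SYN0018	pk_pd	effect	increased
SLC29A4	SYN0019	pk_pd	effect	increased
SLC29A4	SYN0020	pk_pd	effect	increased
DDIT3	SYN0021	pk_pd	effect	increased
DDIT3	SYN0022	pk_pd	effect	increased
FBP1	SYN0023	pk_pd	effect	increased
FBP1	SYN0024	pk_pd	effect	increased
FOXO3	SYN0025	pk_pd	effect	increased
FOXO3	SYN0026	pk_pd	effect	increased
I2BR	SYN0027	pk_pd	effect	increased
I2BR	SYN0028	pk_pd	effect	increased
INS	SYN0029	pk_pd	effect	increased
INS	SYN0030	pk_pd	effect	increased
RPS6KB1	SYN0031	pk_pd	effect	increased
RPS6KB1	SYN0032	pk_pd	effect	increased
INSR	SYN0033	pk_pd	effect	increased
INSR	SYN0034	pk_pd	effect	increased
IRS2	SYN0035	pk_pd	effect	increased
IRS2	SYN0036	pk_pd	effect	increased
KAT2A	SYN0037	pk_pd	effect	increased
KAT2A	SYN0038	pk_pd	effect	increased
KLF15	SYN0039	pk_pd	effect	increased
KLF15	SYN0040	pk_pd	effect	increased
NR0B2	SYN0041	pk_pd	effect	increased
NR0B2	SYN0042	pk_pd	effect	increased
SIRT1	SYN0043	pk_pd	effect	increased
SIRT1	SYN0044	pk_pd	effect	increased
MTOR	SYN0045	molecular_cellular	effect	increased
MTOR	SYN0046	molecular_cellular	effect	increased
SERPINE1	SYN0047	molecular_cellular	effect	increased
SERPINE1	SYN0048	molecular_cellular	effect	increased
AKT1	SYN0049	molecular_cellular	effect	increased
AKT1	SYN0050	molecular_cellular	effect	increased
SLC2A2	SYN0051	molecular_cellular	effect	increased
SLC2A2	SYN0052	molecular_cellular	effect	increased
PIK3	SYN0053	molecular_cellular	effect	increased
PIK3	SYN0054	molecular_cellular	effect	increased
CFTR	SYN0055	molecular_cellular	effect	increased
CFTR	SYN0056	molecular_cellular	effect	increased
ERBB2	SYN0057	molecular_cellular	effect	increased
ERBB2	SYN0058	molecular_cellular	effect	increased
G6PC	SYN0059	molecular_cellular	effect	increased
G6PC	SYN0060	molecular_cellular	effect	increased
GLP1	SYN0061	molecular_cellular	effect	increased
GLP1	SYN0062	molecular_cellular	effect	increased
HIF1A	SYN0063	molecular_cellular	effect	increased
HIF1A	SYN0064	molecular_cellular	effect	increased
IL6	SYN0065	molecular_cellular	effect	increased
IL6	SYN0066	molecular_cellular	effect	increased
PCK1	SYN0067	molecular_cellular	effect	increased
PCK1	SYN0068	molecular_cellular	effect	increased
PCK2	SYN0069	molecular_cellular	effect	increased
PCK2	SYN0070	molecular_cellular	effect	increased
RPS6KB1	SYN0071	molecular_cellular	effect	increased
RPS6KB1	SYN0072	molecular_cellular	effect	increased
TXNIP	SYN0073	molecular_cellular	effect	increased
TXNIP	SYN0074	molecular_cellular	effect	increased
COX2	SYN0075	molecular_cellular	effect	increased
COX2	SYN0076	molecular_cellular	effect	increased
CYP3A4	SYN0077	molecular_cellular	effect	increased
CYP3A4	SYN0078	molecular_cellular	effect	increased
IGFBP1	SYN0079	molecular_cellular	effect	increased
IGFBP1	SYN0080	molecular_cellular	effect	increased
MAPK1	SYN0081	molecular_cellular	effect	increased
MAPK1	SYN0082	molecular_cellular	effect	increased
MAPK3	SYN0083	molecular_cellular	effect	increased
MAPK3	SYN0084	molecular_cellular	effect	increased
PPARGC1A	SYN0085	molecular_cellular	effect	increased
PPARGC1A	SYN0086	molecular_cellular	effect	increased
SREBF1	SYN0087	molecular_cellular	effect	increased
SREBF1	SYN0088	molecular_cellular	effect	increased
AGER	SYN0089	molecular_cellular	effect	increased
AGER	SYN0090	molecular_cellular	effect	increased
BGLAP	SYN0091	molecular_cellular	effect	increased
BGLAP	SYN0092	molecular_cellular	effect	increased
GAPDH	SYN0093	molecular_cellular	effect	increased
GAPDH	SYN0094	molecular_cellular	effect	increased
KLF15	SYN0095	molecular_cellular	effect	increased
KLF15	SYN0096	molecular_cellular	effect	increased
MYC	SYN0097	molecular_cellular	effect	increased
MYC	SYN0098	molecular_cellular	effect	increased
SEPP1	SYN0099	molecular_cellular	effect	increased
SEPP1	SYN0100	molecular_cellular	effect	increased
ABCB1	SYN0101	molecular_cellular	effect	increased
ABCB1	SYN0102	molecular_cellular	effect	increased
ALPP	SYN0103	molecular_cellular	effect	increased
ALPP	SYN0104	molecular_cellular	effect	increased
CASP3	SYN0105	molecular_cellular	effect	increased
CASP3	SYN0106	molecular_cellular	effect	increased
CCNE1	SYN0107	molecular_cellular	effect	increased
CCNE1	SYN0108	molecular_cellular	effect	increased
CYP19A1	SYN0109	molecular_cellular	effect	increased
CYP19A1	SYN0110	molecular_cellular	effect	increased
DDIT4	SYN0111	molecular_cellular	effect	increased
DDIT4	SYN0112	molecular_cellular	effect	increased
IL1RN	SYN0113	molecular_cellular	effect	increased
IL1RN	SYN0114	molecular_cellular	effect	increased
IRS2	SYN0115	molecular_cellular	effect	increased
IRS2	SYN0116	molecular_cellular	effect	increased
SLC2A4	SYN0117	molecular_cellular	effect	increased
SLC2A4	SYN0118	molecular_cellular	effect	increased
MAPK8	SYN0119	molecular_cellular	effect	increased
MAPK8	SYN0120	molecular_cellular	effect	increased
MEF2A	SYN0121	molecular_cellular	effect	increased
MEF2A	SYN0122	molecular_cellular	effect	increased
NFKB	SYN0123	molecular_cellular	effect	increased
NFKB	SYN0124	molecular_cellular	effect	increased
NR1I2	SYN0125	molecular_cellular	effect	increased
NR1I2	SYN0126	molecular_cellular	effect	increased
PKLR	SYN0127	molecular_cellular	effect	increased
PKLR	SYN0128	molecular_cellular	effect	increased
PPARA	SYN0129	molecular_cellular	effect	increased
PPARA	SYN0130	molecular_cellular	effect	increased
PPP2R4	SYN0131	molecular_cellular	effect	increased
PPP2R4	SYN0132	molecular_cellular	effect	increased
RAB4A	SYN0133	molecular_cellular	effect	increased
RAB4A	SYN0134	molecular_cellular	effect	increased
STAT3	SYN0135	molecular_cellular	effect	increased
STAT3	SYN0136	molecular_cellular	effect	increased
TNFA	SYN0137	molecular_cellular	effect	increased
TNFA	SYN0138	molecular_cellular	effect	increased
TP53	SYN0139	molecular_cellular	effect	increased
TP53	SYN0140	molecular_cellular	effect	increased
TSC1	SYN0141	molecular_cellular	effect	increased
TSC1	SYN0142	molecular_cellular	effect	increased
TSC2	SYN0143	molecular_cellular	effect	increased
TSC2	SYN0144	molecular_cellular	effect	increased
TIMP2	SYN0145	molecular_cellular	effect	increased
TIMP2	SYN0146	molecular_cellular	effect	increased
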