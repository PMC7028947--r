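gene	role	ddr_pathway
ATM	tumour_suppressor	checkpoint
ATR	tumour_suppressor	checkpoint
CHEK1	tumour_suppressor	checkpoint
CHEK2	tumour_suppressor	checkpoint
BRCA1	tumour_suppressor	HR
BRCA2	tumour_suppressor	HR
PALB2	tumour_suppressor	HR
BAP1	tumour_suppressor	HR
BARD1	tumour_suppressor	HR
BRIP1	tumour_suppressor	HR
RAD50	tumour_suppressor	HR
RAD51	tumour_suppressor	HR
RAD51B	tumour_suppressor	HR
RAD51C	tumour_suppressor	HR
RAD51D	tumour_suppressor	HR
MRE11	tumour_suppressor	HR
NBN	tumour_suppressor	HR
FANCA	tumour_suppressor	FA
FANCC	tumour_suppressor	FA
FANCD2	tumour_suppressor	FA
ERCC2	tumour_suppressor	NER
ERCC3	tumour_suppressor	NER
ERCC4	tumour_suppressor	NER
ERCC5	tumour_suppressor	NER
ERCC6	tumour_suppressor	NER
MLH1	tumour_suppressor	MMR
MSH2	tumour_suppressor	MMR
MSH6	tumour_suppressor	MMR
PMS2	tumour_suppressor	MMR
POLE	tumour_suppressor	other
TP53	tumour_suppressor	none
RB1	tumour_suppressor	none
CDKN2A	tumour_suppressor	none
CDKN2B	tumour_suppressor	none
PTEN	tumour_suppressor	none
ARID1A	tumour_suppressor	none
KDM6A	tumour_suppressor	none
STAG2	tumour_suppressor	none
TSC1	tumour_suppressor	none
KMT2D	tumour_suppressor	none
KMT2C	tumour_suppressor	none
CREBBP	tumour_suppressor	none
EP300	tumour_suppressor	none
FBXW7	tumour_suppressor	none
NF1	tumour_suppressor	none
ELF3	tumour_suppressor	none
RHOB	unknown	none
ZFHX3	tumour_suppressor	none
ERBB2	oncogene	none
ERBB3	oncogene	none
FGFR3	oncogene	none
PIK3CA	oncogene	none
CCND1	oncogene	none
CCNE1	oncogene	none
MDM2	oncogene	none
EGFR	oncogene	none
MYC	oncogene	none
MYCL	oncogene	none
KRAS	oncogene	none
HRAS	oncogene	none
AKT1	oncogene	none
NFE2L2	oncogene	none
TERT	oncogene	none
MTOR	both	none
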