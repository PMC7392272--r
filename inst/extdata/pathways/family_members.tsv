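token	members	note
CSF1-CSF1R	CSF1;CSF1R	ligand-receptor axis
GRB2	GRB2
SOS1/2	SOS1;SOS2
KRAS/NRAS	KRAS;NRAS
ARAF/RAF1	ARAF;RAF1
MAP2K1/2	MAP2K1;MAP2K2
MAPK1/3	MAPK1;MAPK3
ATF4/ELK4/MYC	ATF4;ELK4;MYC
SRF/FOS	SRF;FOS
MAP3K1	MAP3K1
MAP2K4	MAP2K4
MAPK8/9/10	MAPK8;MAPK9;MAPK10
FOS	FOS
JUND	JUND
CD14	CD14
TAB1/2	TAB1;TAB2
MAP3K7	MAP3K7
IKBKG	IKBKG
NFKB1/2	NFKB1;NFKB2
RELA/RELB	RELA;RELB
NF2	NF2
SAV1	SAV1
LATS1/2	LATS1;LATS2
YAP1/WWTR1	YAP1;WWTR1
TGFB	TGFB1	figure labels TGFB1
SMAD	SMAD2;SMAD3	family-level node; no members enumerated in the source description
FGF1	FGF1
ITGB2	ITGB2
NPPA	NPPA
ADYCYAPR1R1	ADCYAP1R1	symbol variant in the source description
GNAS	GNAS
ADYC5/6	ADCY5;ADCY6	symbol variant of ADCY5/6
PRKCA/B/C	PRKCA;PRKCB;PRKCG	the gamma isoform symbol is PRKCG
RAPGEF3/4	RAPGEF3;RAPGEF4
RAP1A/B	RAP1A;RAP1B
JUN	JUN
AFDN	AFDN
VAV2	VAV2
RAC1	RAC1
PAK1	PAK1
PI3K	PIK3CA;PIK3CB	class I catalytic subunits
AKT1/2/3	AKT1;AKT2;AKT3
PPP1CA/B/C	PPP1CA;PPP1CB;PPP1CC
CREB	CREB1
JAK1/2	JAK1;JAK2	receptor-associated kinases; figure-level node
STAT3	STAT3
PIM1	PIM1
MYC	MYC
CCND1/2/3	CCND1;CCND2;CCND3
PTPN11/GRB	PTPN11;GRB2	truncated GRB2 in the source description
HRAS	HRAS
RAF1	RAF1
MTOR	MTOR
NFKB1/RELA	NFKB1;RELA
NKF1B	NFKB1	presumed typo for NFKB1
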