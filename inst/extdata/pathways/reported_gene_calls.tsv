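gene_id	passes_abundance	early_up	late_up	late_down
CSF1	TRUE	TRUE	TRUE	FALSE
CSF1R	TRUE	TRUE	TRUE	FALSE
CD14	TRUE	TRUE	TRUE	FALSE
GRB2	TRUE	TRUE	FALSE	FALSE
SOS1	TRUE	TRUE	FALSE	FALSE
SOS2	TRUE	TRUE	FALSE	FALSE
KRAS	TRUE	TRUE	FALSE	FALSE
NRAS	TRUE	TRUE	FALSE	FALSE
ARAF	TRUE	TRUE	FALSE	FALSE
RAF1	TRUE	TRUE	TRUE	FALSE
MAP2K1	TRUE	TRUE	FALSE	FALSE
MAP2K2	TRUE	TRUE	FALSE	FALSE
MAPK1	TRUE	TRUE	FALSE	FALSE
MAPK3	TRUE	TRUE	FALSE	FALSE
ATF4	TRUE	TRUE	TRUE	FALSE
ELK4	TRUE	TRUE	FALSE	FALSE
MYC	TRUE	TRUE	TRUE	FALSE
SRF	TRUE	TRUE	FALSE	FALSE
FOS	TRUE	TRUE	TRUE	FALSE
MAP3K1	TRUE	TRUE	FALSE	FALSE
MAP2K4	TRUE	TRUE	FALSE	FALSE
MAPK8	TRUE	TRUE	FALSE	FALSE
MAPK9	TRUE	TRUE	FALSE	FALSE
MAPK10	TRUE	TRUE	FALSE	FALSE
JUND	TRUE	TRUE	TRUE	FALSE
TAB1	TRUE	TRUE	FALSE	FALSE
TAB2	TRUE	TRUE	FALSE	FALSE
MAP3K7	TRUE	TRUE	FALSE	FALSE
IKBKG	TRUE	TRUE	FALSE	FALSE
NFKB1	TRUE	TRUE	TRUE	FALSE
NFKB2	TRUE	TRUE	TRUE	FALSE
RELA	TRUE	TRUE	TRUE	FALSE
RELB	TRUE	TRUE	TRUE	FALSE
NF2	TRUE	TRUE	FALSE	FALSE
SAV1	TRUE	TRUE	FALSE	FALSE
LATS1	TRUE	TRUE	FALSE	FALSE
LATS2	TRUE	TRUE	FALSE	FALSE
YAP1	TRUE	FALSE	FALSE	FALSE
WWTR1	TRUE	FALSE	FALSE	FALSE
TGFB1	TRUE	TRUE	TRUE	FALSE
SMAD2	TRUE	TRUE	FALSE	FALSE
SMAD3	TRUE	TRUE	FALSE	FALSE
FGF1	TRUE	TRUE	FALSE	FALSE
ITGB2	TRUE	TRUE	TRUE	FALSE
NPPA	TRUE	TRUE	TRUE	FALSE
ADCYAP1R1	TRUE	TRUE	FALSE	FALSE
GNAS	TRUE	TRUE	FALSE	FALSE
ADCY5	TRUE	TRUE	FALSE	FALSE
ADCY6	TRUE	TRUE	FALSE	FALSE
PRKCA	TRUE	TRUE	FALSE	FALSE
PRKCB	TRUE	TRUE	FALSE	FALSE
PRKCG	TRUE	TRUE	FALSE	FALSE
RAPGEF3	TRUE	TRUE	FALSE	FALSE
RAPGEF4	TRUE	TRUE	FALSE	FALSE
RAP1A	TRUE	TRUE	FALSE	FALSE
RAP1B	TRUE	TRUE	FALSE	FALSE
JUN	TRUE	TRUE	TRUE	FALSE
AFDN	TRUE	TRUE	FALSE	FALSE
VAV2	TRUE	TRUE	FALSE	FALSE
RAC1	TRUE	TRUE	FALSE	FALSE
PAK1	TRUE	TRUE	FALSE	FALSE
PIK3CA	TRUE	TRUE	FALSE	FALSE
PIK3CB	TRUE	TRUE	FALSE	FALSE
AKT1	TRUE	TRUE	FALSE	FALSE
AKT2	TRUE	TRUE	FALSE	FALSE
AKT3	TRUE	TRUE	FALSE	FALSE
PPP1CA	TRUE	TRUE	FALSE	FALSE
PPP1CB	TRUE	TRUE	FALSE	FALSE
PPP1CC	TRUE	TRUE	FALSE	FALSE
CREB1	TRUE	FALSE	FALSE	TRUE
JAK1	TRUE	TRUE	FALSE	FALSE
JAK2	TRUE	TRUE	FALSE	FALSE
STAT3	TRUE	TRUE	FALSE	FALSE
PIM1	TRUE	TRUE	TRUE	FALSE
CCND1	TRUE	TRUE	TRUE	FALSE
CCND2	TRUE	TRUE	TRUE	FALSE
CCND3	TRUE	TRUE	TRUE	FALSE
PTPN11	TRUE	TRUE	FALSE	FALSE
HRAS	TRUE	TRUE	FALSE	FALSE
MTOR	TRUE	TRUE	TRUE	FALSE
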