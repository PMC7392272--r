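pathway_id	token
mapk	CSF1-CSF1R
mapk	GRB2
mapk	SOS1/2
mapk	KRAS/NRAS
mapk	ARAF/RAF1
mapk	MAP2K1/2
mapk	MAPK1/3
mapk	ATF4/ELK4/MYC
mapk	SRF/FOS
mapk	MAP3K1
mapk	MAP2K4
mapk	MAPK8/9/10
mapk	FOS
mapk	JUND
mapk	CD14
mapk	TAB1/2
mapk	MAP3K7
mapk	IKBKG
mapk	NFKB1/2
mapk	RELA/RELB
hippo	NF2
hippo	SAV1
hippo	LATS1/2
hippo	YAP1/WWTR1
hippo	TGFB
hippo	SMAD
hippo	FGF1
hippo	ITGB2
camp	NPPA
camp	ADYCYAPR1R1
camp	GNAS
camp	ADYC5/6
camp	PRKCA/B/C
camp	RAPGEF3/4
camp	RAP1A/B
camp	MAP2K1/2
camp	MAPK1/3
camp	JUN
camp	FOS
camp	AFDN
camp	VAV2
camp	RAC1
camp	PAK1
camp	PI3K
camp	AKT1/2/3
camp	PPP1CA/B/C
camp	CREB
jak_stat	CSF1-CSF1R
jak_stat	JAK1/2
jak_stat	STAT3
jak_stat	PIM1
jak_stat	MYC
jak_stat	CCND1/2/3
jak_stat	PTPN11/GRB
jak_stat	SOS1/2
jak_stat	HRAS
jak_stat	RAF1
jak_stat	PI3K
jak_stat	AKT1/2/3
jak_stat	MTOR
ras	CSF1-CSF1R
ras	AFDN
ras	PI3K
ras	AKT1/2/3
ras	IKBKG
ras	NFKB1/RELA
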