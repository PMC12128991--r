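# Default CHIP driver gene list (78 symbols, one per line, editable).
# Curated from established clonal-hematopoiesis driver panels.
DNMT3A
TET2
ASXL1
JAK2
TP53
PPM1D
SF3B1
SRSF2
U2AF1
U2AF2
IDH1
IDH2
CBL
CBLB
KRAS
NRAS
GNAS
GNB1
BCOR
BCORL1
STAG2
RAD21
SMC1A
SMC3
EZH2
KDM6A
KMT2A
KMT2D
CREBBP
EP300
RUNX1
ETV6
GATA2
GATA3
CEBPA
FLT3
KIT
MPL
CALR
CSF1R
CSF3R
SETBP1
PHF6
WT1
BRAF
PTPN11
NF1
SH2B3
LUC7L2
ZRSR2
PRPF8
DDX41
SETD2
ASXL2
SUZ12
EED
JARID2
ATM
CHEK2
PDS5B
CTCF
NPM1
STAT3
STAT5B
MYD88
CARD11
PIK3CA
PIK3R1
MGA
RIT1
CUX1
IKZF1
IKZF2
IKZF3
PAX5
ZBTB33
SRCAP
YLPM1
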