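P2RY12
TMEM119
CX3CR1
TREM2
GPR34
OLFML3
SALL1
HEXB
TYROBP
P2RY13
SIGLEC11
SLC2A5
TGFBR1
MERTK
PROS1
GAS6
ITGAM
AIF1
CSF1R
IRF8
SPI1
CD33
CD68
TLR4
MRC1
C1QA
C1QB
C1QC
CTSS
FCGR1A
LAPTM5
LY86
CD74
TREM1
APOE
GRN
LRRK2
SORL1
ABI3
BIN1
PLCG2
INPP5D
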