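# Synthetic stand-in for a DNA damage response annotation set.
# Hand-picked core DDR gene symbols for examples and tests; this is NOT a
# snapshot of any pathway database.
ATM
ATR
BRCA1
BRCA2
PALB2
RAD51
RAD51B
RAD51C
RAD51D
RAD52
RAD54L
BARD1
BRIP1
CHEK1
CHEK2
FANCA
FANCB
FANCC
FANCD2
FANCE
FANCF
FANCG
FANCI
FANCL
FANCM
MDC1
MRE11
NBN
RBBP8
TP53BP1
SHLD1
SHLD2
SHLD3
RIF1
XRCC1
XRCC2
XRCC3
XRCC4
LIG4
PRKDC
POLQ
PARP1
PARP2
TOPBP1
CLSPN
BLM
WRN
RECQL5
EXO1
MUS81
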