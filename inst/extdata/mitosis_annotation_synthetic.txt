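# Synthetic curated annotation mask: genes regulating mechanisms during
# mitosis (spindle assembly, chromosome segregation, mitotic exit).
# Constructed stand-in for a curated mitosis-regulator list; used as the
# external annotation input of the signature-distillation step.
PBK
CEP55
UBE2C
MELK
TPX2
PTTG1
CDCA3
CCNB1
CCNB2
CDC20
AURKA
AURKB
BUB1
PLK1
MAD2L1
TTK
ESPL1
CDCA8
NEK2
KIF20A
ECT2
PRC1
CDK1
FOXM1
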