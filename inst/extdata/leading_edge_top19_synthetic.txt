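# Synthetic reconstruction of a top-19 CIN70 leading edge for the
# signature-distillation worked example. Only the seven mitotic genes of
# the distilled PC-CIN signature are known members of the source list;
# the remaining twelve are CIN70 replication/repair/chromatin genes used
# as plausible non-mitotic context. Order is rank order in the synthetic
# ranking. This file is a constructed stand-in, not published data.
TPX2
PCNA
UBE2C
MCM2
PBK
FEN1
CEP55
RRM2
MELK
RFC4
PTTG1
MCM7
CDCA3
MSH6
UNG
DKC1
EZH2
ATAD2
RRM1
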