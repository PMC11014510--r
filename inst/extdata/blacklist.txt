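# gene families with unreliable one-to-one orthology in alignment-based
# annotation: excluded before phylogenetic and enrichment analyses
C*orf*
DEFB*
FAM*
HIST*
KRT*
KRTAP*
NPIPA*
NPIPB*
PRAME*
SLC*
SPATA*
USP*
ZFP*
ZSCAN*
UGT*
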