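# Compact default immune-related gene list (one symbol per line).
# The eight published immune-signature genes plus common immune and
# endothelial markers; substitute a full a-priori list for real analyses.
ITLN2
MARCO
C8B
MASP1
CD36
TAL1
PPBP
CDH5
CD8A
CD8B
CD4
FOXP3
GZMB
PRF1
NKG7
KLRD1
CCL5
CXCL9
CXCL10
IL2RB
PTPRC
CD19
MS4A1
CD68
CD163
ITGAM
VWF
PECAM1
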