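gene	role
BCL2L15	tumor
COMP	tumor
CST1	tumor
FAM83A	tumor
ITLN2	immune
MARCO	immune
C8B	immune
MASP1	immune
CD36	immune
TAL1	immune
PPBP	immune
CDH5	immune
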