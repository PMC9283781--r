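# Default common tumor-suppressor gene list (configurable).
TP53
RB1
STK11
NF1
KEAP1
PTEN
CDKN2A
SMAD4
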