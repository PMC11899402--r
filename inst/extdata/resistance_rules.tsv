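gene	class
B2M	lof
TP53	lof
STK11	lof
PTEN	lof
KRAS	nonsyn
MDM2	amp
MDM4	amp
EGFR	amp
JAK1	nonsyn
JAK2	nonsyn
CTNNB1	nonsyn
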