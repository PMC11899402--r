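TGFB1
IL10
VEGFA
FOXP3
CCL2
CD163
MSR1
ARG1
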