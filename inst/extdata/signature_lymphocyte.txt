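CD3D
CD3E
CD2
CD8A
CD8B
PTPRC
CD19
MS4A1
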