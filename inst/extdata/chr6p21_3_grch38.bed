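chr6	28510020	33480577	MHC_class_I_region
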