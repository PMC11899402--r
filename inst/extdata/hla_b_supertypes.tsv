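allele	supertype
B*14:02	B27
B*15:09	B27
B*15:10	B27
B*27:02	B27
B*27:03	B27
B*27:04	B27
B*27:05	B27
B*27:06	B27
B*38:01	B27
B*39:01	B27
B*39:09	B27
B*48:01	B27
B*73:01	B27
B*18:01	B44
B*37:01	B44
B*40:01	B44
B*40:02	B44
B*40:06	B44
B*44:02	B44
B*44:03	B44
B*45:01	B44
B*49:01	B44
B*50:01	B44
B*13:02	B62
B*15:01	B62
B*15:02	B62
B*15:12	B62
B*15:13	B62
B*15:16	B62
B*46:01	B62
B*52:01	B62
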