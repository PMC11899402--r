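allele	sequence
A*01:01	SDEESSSLHIDDFYQAPMTFSMFDYQEDIMYGKGDIFRPSHNAWCELQVK
A*02:01	GNVESHSLHGDTAYHAPMRFSMHDYEEDIMYGMTDIRHPSCNLWCELQVK
A*03:01	GDYESQSLHEDDAYHAPMRFSMHNYAEDVMYGMGDIFHPGHNLCCELLVK
A*11:01	GDYESQSLHEDDAYHAPMRFSMHDYFEDIMYGMGKIFHPSHYLPCELQVN
A*24:02	GDYCSQSLHEDDAYHAPMKFSMHDYAEDIDYSMPDHFHPSKNLWEELQVK
A*26:01	GDYESQQPHEMDYYHAPMVFSMHDYAEDICYGMGDIFHPSHNLWQELQLK
B*07:02	GPMGYLWPASKIYPMMQKGENSWMPTNMAFISEKQLVFVNMQDWEGQEFM
B*08:01	GPSGYLWPASVIYIMMVKEENSWMYPNMAFKREKQLVNVNMQDIEGQEFM
B*15:01	GPSGYLMRASKIYNMMKKEENSWMYVNMAFFLEKQAVNVNMQDIEGQEFP
B*27:05	GGSGYLLPASKIYQMMVKEEWSWTYVTMAIQLEKQLVNVKMQDIEGQEFA
B*35:01	GPSGYLWPASKLNNMMVKEEASWMYVNMAFELEKQLENVNMQDTERTEFN
B*40:01	APSGYTWPASVIYIMMILEENSWMYVNMGFFLEKWFVNVNPQDIEGQPFM
B*44:02	GDSGYLWPHSKICNMMVKEENSWMMVNMAFFLEVQLVNVNMQDINGQEFM
B*57:01	GPSGYLWPASKIVNMMVKSENGWMYVNMAAFLEAQLVNVNMQDIEGQEFM
C*01:02	DCHQFISNESQVHFCSKGKLDMVAWCIQGYSPGSNYGKYRNHWGIHLLQW
C*03:04	DCHQFHSNEEQVGFWSKSKLDMGAWCIQGQSFGSNKGKYTNHWIIYRLQW
C*04:01	DCHQFIINEEQVEFWSKSKLDMVAWCIQYYSFISNKGKYTNHSIIYRLQW
C*05:01	DMHEFISNAEQVEFDSKRKLDMVAWCIQGYDFGSNKGVYTNHWIIYRLTW
C*07:01	DCHQFISNEEQVNFWSKSKLDMVAWIWQGYSFGSPKFKYTNHWIIYRLQS
C*07:02	DCHQFISNEEQVEFWSKSKLDLVSWCIQGYSFGSNKAKYRNHWTIYRLQW
C*16:01	DCVQFISNEEQEEFWSKSKLDMKAWCDAGYSFDQNKGKYTNNWIIYRLRW
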