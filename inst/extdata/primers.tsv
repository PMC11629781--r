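name	direction	sequence
mlCOIintF	forward	GGWACWGGWTGAACWGTWTAYCCYCC
mlCOIintF-XT	forward	GGWACWRGWTGRACWITITAYCCYCC
HCO2198	reverse	TAAACTTCAGGGTGACCAAAAAATCA
dgHCO2198	reverse	TAAACTTCAGGGTGACCAAARAAYCA
jgHCO2198	reverse	TAIACYTCIGGRTGICCRAARAAYCA
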