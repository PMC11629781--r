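name	forward	reverse
Leray-Folmer	mlCOIintF	HCO2198
Leray-Meyer	mlCOIintF	dgHCO2198
Leray-Geller	mlCOIintF	jgHCO2198
Leray XT	mlCOIintF-XT	jgHCO2198
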