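protein	molar_mass_min	molar_mass_max	c_prot_min	c_prot_max	is_casein
CASA1	18629	22975	10	15	TRUE
CASA2	23322	24349	3	4	TRUE
CASB	22641	23623	9	11	TRUE
CASK	18858	18974	3	4	TRUE
LACB	18168	18375	3	4	FALSE
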