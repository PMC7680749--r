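# Reference per-peptide TCMP results for an incurred baked-cookie sample at a
# nominal level of 10.7 mg total milk protein per kg (reported study values;
# w_tcmp and U in mg/kg, U at k = 2, u_rel at k = 1, indexes in % of the
# combined variance).
protein	peptide	w_tcmp	U_k2	u_rel_pct	idx_f_purity	idx_b_pep	idx_M	idx_f_ext	idx_f_dig	idx_CF
CASA1	FFV	6.81	2.01	15	0.6	0.4	17	10	0.0	72
CASA1	YLG	9.41	2.88	15	3.8	11	16	2.1	0.0	67
CASA2	ALN	5.41	1.26	12	4.7	6.1	1.1	17	0.5	71
CASA2	FAL	4.66	1.18	13	1.2	11	1.0	28	0.0	60
CASA2	NAV	6.04	1.33	11	1.6	0.8	1.3	17	0.0	79
CASA2	VIP	4.72	1.17	12	0.8	16	1.0	20	0.0	62
CASB	AVP	13.0	3.0	12	1.2	20	1.1	29	2.7	46
CASB	VLP	11.4	2.3	10	1.7	10	1.5	17	7.9	62
CASK	YIP	10.7	2.5	12	2.7	0.7	0.0	28	0.0	68
LACB	ALP	5.43	1.38	13	2.0	21	0.1	9.4	8.5	59
LACB	IPA	3.17	0.78	12	0.8	28	0.1	5.1	3.2	63
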