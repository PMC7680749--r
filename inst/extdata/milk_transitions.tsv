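protein	peptide	label	rt_min	precursor_mz	product_mz	ion	ce	cone	stated_mh	note
CASA1	FFVAPFPEVFGK	natural	19.6	693.0	465.2	b4	14	25	1383.746	stated mass matches neither neutral nor MH+
CASA1	FFVAPFPEVFGK	natural	19.6	693.0	920.4	y8	18	25	1383.746	stated mass matches neither neutral nor MH+
CASA1	FFVAPFPEVFGK	sil	19.6	697.0	928.4	y8	18	25	1391.746	
CASA1	YLGYLEQLLR	natural	18.0	634.5	771.3	y6	16	25	1267.704	
CASA1	YLGYLEQLLR	natural	18.0	634.5	991.3	y8	20	25	1267.704	
CASA1	YLGYLEQLLR	sil	18.0	639.5	1001.3	y8	20	25	1277.704	
CASA2	ALNEINQFYQK	natural	10.4	684.4	438.1	b4	20	15	1366.688	sequence elsewhere listed as ALNEINQFYQR; stated mass and +8 SIL shift match the C-terminal-K form
CASA2	ALNEINQFYQK	natural	10.4	684.4	827.4	y6	20	15	1366.688	sequence elsewhere listed as ALNEINQFYQR; stated mass and +8 SIL shift match the C-terminal-K form
CASA2	ALNEINQFYQK	sil	10.4	688.4	835.4	y6	20	15	1374.688	
CASA2	FALPQYLK	natural	13.0	490.3	648.3	y5	14	15	979.561	
CASA2	FALPQYLK	natural	13.0	490.3	761.3	y6	14	15	979.561	
CASA2	FALPQYLK	sil	13.0	494.3	656.3	y5	14	15	987.561	
CASA2	NAVPITPTLNR	natural	9.6	598.3	701.4	y6	20	15	1195.679	
CASA2	NAVPITPTLNR	natural	9.6	598.3	911.4	y8	15	15	1195.679	
CASA2	NAVPITPTLNR	sil	9.6	603.3	921.4	y8	15	15	1205.679	
CASA2	VIPYVR	natural	7.4	373.8	437.4	y3	15	15	746.455	sequence sometimes printed as VIPYVPR; stated mass matches VIPYVR
CASA2	VIPYVR	natural	7.4	373.8	534.4	y4	15	15	746.455	sequence sometimes printed as VIPYVPR; stated mass matches VIPYVR
CASA2	VIPYVR	sil	7.4	378.7	544.4	y4	15	15	756.455	
CASB	AVPYPQR	natural	4.7	415.8	400.2	y3	15	20	830.452	
CASB	AVPYPQR	natural	4.7	415.8	660.3	y5	15	20	830.452	
CASB	AVPYPQR	sil	4.7	420.8	670.3	y5	15	20	838.452	
CASB	VLPVPQK	natural	6.0	390.8	372.2	y3	15	20	779.490	
CASB	VLPVPQK	natural	6.0	390.8	568.2	y5	10	20	779.490	
CASB	VLPVPQK	sil	6.0	394.8	380.2	y3	15	20	787.490	
CASK	YIPIQYVLSR	natural	15.1	626.5	488.2	b4	20	25	1251.710	
CASK	YIPIQYVLSR	natural	15.1	626.5	765.2	y6	20	25	1251.710	
CASK	YIPIQYVLSR	sil	15.1	631.5	493.2	b4	20	25	1259.710	
LACB	ALPMHIR	natural	6.6	419.8	425.3	y3	15	26	837.476	printed precursor m/z sits ~0.56 Th above the 2+ m/z of the stated monoisotopic mass
LACB	ALPMHIR	natural	6.6	419.8	653.5	y5	15	26	837.476	printed precursor m/z sits ~0.56 Th above the 2+ m/z of the stated monoisotopic mass
LACB	ALPMHIR	sil	6.6	424.8	663.5	y5	15	25	837.476	stated SIL mass equals the natural mass (print error; computed 847.476); printed precursor m/z sits ~0.56 Th above the 2+ m/z of the stated monoisotopic mass
LACB	IPAVFK	natural	8.1	337.8	393.2	y3	15	25	674.424	
LACB	IPAVFK	natural	8.1	337.8	464.2	y4	15	25	674.424	
LACB	IPAVFK	sil	8.1	341.8	472.2	y4	15	15	682.424	
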