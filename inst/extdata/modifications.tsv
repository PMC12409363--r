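trna_id	position_label	mod_name	mass_delta_avg_da
Eco-Lys-UUU	8	s4U	16.061
Eco-Lys-UUU	16	D	2.016
Eco-Lys-UUU	17	D	2.016
Eco-Lys-UUU	20	D	2.016
Eco-Lys-UUU	34	mnm5s2U	59.131
Eco-Lys-UUU	37	ct6A	127.099
Eco-Lys-UUU	39	Y	0.000
Eco-Lys-UUU	46	m7G	14.027
Eco-Lys-UUU	54	m5U	14.027
Eco-Lys-UUU	55	Y	0.000
Eco-Thr-UGU	8	s4U	16.061
Eco-Thr-UGU	16	D	2.016
Eco-Thr-UGU	18	Gm	14.027
Eco-Thr-UGU	20	D	2.016
Eco-Thr-UGU	34	mnm5U	43.069
Eco-Thr-UGU	37	t6A	145.114
Eco-Thr-UGU	39	Y	0.000
Eco-Thr-UGU	46	m7G	14.027
Eco-Thr-UGU	54	m5U	14.027
Eco-Thr-UGU	55	Y	0.000
Eco-Asn-GUU	8	s4U	16.061
Eco-Asn-GUU	17	D	2.016
Eco-Asn-GUU	20	D	2.016
Eco-Asn-GUU	34	Q	115.110
Eco-Asn-GUU	37	t6A	145.114
Eco-Asn-GUU	39	Y	0.000
Eco-Asn-GUU	46	m7G	14.027
Eco-Asn-GUU	47	acp3U	101.105
Eco-Asn-GUU	54	m5U	14.027
Eco-Asn-GUU	55	Y	0.000
Eco-Thr-CGU	8	s4U	16.061
Eco-Thr-CGU	16	D	2.016
Eco-Thr-CGU	20	D	2.016
Eco-Thr-CGU	37	m2A	14.027
Eco-Thr-CGU	39	Y	0.000
Eco-Thr-CGU	46	m7G	14.027
Eco-Thr-CGU	54	m5U	14.027
Eco-Thr-CGU	55	Y	0.000
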