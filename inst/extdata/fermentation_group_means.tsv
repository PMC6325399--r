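species	diet	pH	NH3N_mg_dL	total_VFA_mM	acetate	propionate	butyrate	isobutyrate	valerate	isovalerate	AP_ratio
Hanwoo	HF	6.39	1.27	74.3	590	175	123	59	28	25	3.4
Hanwoo	HC	5.56	4.97	81.5	470	272	130	55	46	28	1.8
Holstein	HF	6.37	2.56	63.1	585	170	118	68	31	29	3.5
Holstein	HC	5.14	4.84	121.6	464	210	215	38	55	18	2.5
Goat	HF	6.25	5.19	59.4	562	218	88	71	34	27	2.6
Goat	HC	5.90	7.51	53.8	478	198	164	82	44	35	2.5
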