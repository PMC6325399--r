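species	diet	taxon	abundance_percent
Hanwoo	HF	Prevotella	37.921
Hanwoo	HC	Prevotella	40.747
Holstein	HF	Prevotella	41.885
Holstein	HC	Prevotella	37.905
Goat	HF	Prevotella	39.599
Goat	HC	Prevotella	51.827
Hanwoo	HF	F_succinogenes	0.774
Hanwoo	HC	F_succinogenes	0.039
Holstein	HF	F_succinogenes	0.819
Holstein	HC	F_succinogenes	0.099
Goat	HF	F_succinogenes	2.187
Goat	HC	F_succinogenes	0.171
Hanwoo	HF	R_flavefaciens	0.010
Hanwoo	HC	R_flavefaciens	0.025
Holstein	HF	R_flavefaciens	0.016
Holstein	HC	R_flavefaciens	0.001
Goat	HF	R_flavefaciens	0.008
Goat	HC	R_flavefaciens	0.003
Hanwoo	HF	S_bovis	2.715
Hanwoo	HC	S_bovis	0.020
Holstein	HF	S_bovis	0.782
Holstein	HC	S_bovis	0.011
Goat	HF	S_bovis	0.158
Goat	HC	S_bovis	0.015
Hanwoo	HF	Lactobacillus	0.016
Hanwoo	HC	Lactobacillus	0.380
Holstein	HF	Lactobacillus	0.040
Holstein	HC	Lactobacillus	1.041
Goat	HF	Lactobacillus	0.002
Goat	HC	Lactobacillus	0.862
Hanwoo	HF	S_ruminantium	3.475
Hanwoo	HC	S_ruminantium	3.037
Holstein	HF	S_ruminantium	3.632
Holstein	HC	S_ruminantium	3.169
Goat	HF	S_ruminantium	5.812
Goat	HC	S_ruminantium	3.902
Hanwoo	HF	M_elsdenii	0.001
Hanwoo	HC	M_elsdenii	1.450
Holstein	HF	M_elsdenii	0.002
Holstein	HC	M_elsdenii	3.402
Goat	HF	M_elsdenii	0.001
Goat	HC	M_elsdenii	1.692
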