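genus	species	category	pd	syn_per_kb	nonsyn_fraction	nonsense_fraction	provean_fraction	sift_fraction
Ajuga	A. boninsimae	EIE	0.710	0.022	0.677	0.043	0.459	0.370
Ajuga	A. pygmaea	NE	0.720	0.026	0.654	0.041	0.422	0.354
Ajuga	A. shikotanensis	NE	0.741	0.440	0.503	0.017	0.319	0.200
Crepidiastrum	C. grandicollum	EIE	0.676	0.168	0.601	0.029	0.404	0.261
Crepidiastrum	C. ameristophyllum	EIE	0.721	0.133	0.599	0.024	0.386	0.260
Crepidiastrum	C. linguifolium	EIE	0.687	0.129	0.593	0.030	0.377	0.244
Crepidiastrum	C. lanceolatum	NE	0.759	0.254	0.490	0.020	0.278	0.190
Crepidiastrum	C. keiskeanum	NE	0.717	0.283	0.512	0.017	0.320	0.202
Calanthe	C. hoshii	EIE	0.709	0.128	0.581	0.026	0.357	0.255
Calanthe	C. triplicata	NE	0.752	0.256	0.506	0.023	0.263	0.211
Melastoma	M. tetramerum	EIE	0.701	0.100	0.596	0.019	0.376	0.255
Melastoma	M. candidum	NE	0.704	0.361	0.496	0.013	0.292	0.208
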