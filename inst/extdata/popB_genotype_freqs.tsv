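genotype	rs2856838	rs8193036	rs2243191	rs20541	rs2227306	rs4739139	rs741344	rs583911
CC	0.460	0.159	0.480	0.603	0.567	0.733	0.000	0.000
TC	0.399	0.433	0.353	0.331	0.361	0.242	0.000	0.000
TT	0.141	0.409	0.168	0.066	0.072	0.025	0.000	0.000
AA	0.000	0.000	0.000	0.000	0.000	0.000	0.437	0.377
GA	0.000	0.000	0.000	0.000	0.000	0.000	0.425	0.358
GG	0.000	0.000	0.000	0.000	0.000	0.000	0.139	0.264
Count	652	1817	1934	1247	610	554	504	1468
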