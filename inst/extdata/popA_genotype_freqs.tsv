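genotype	rs2856838	rs8193036	rs2243191	rs20541	rs2227306	rs4739139	rs741344	rs583911
CC	0.562	0.504	0.073	0.477	0.407	0.488	0.000	0.000
CT	0.379	0.407	0.406	0.426	0.476	0.445	0.000	0.000
TT	0.059	0.089	0.521	0.097	0.117	0.067	0.000	0.000
AA	0.000	0.000	0.000	0.000	0.000	0.000	0.427	0.062
AG	0.000	0.000	0.000	0.000	0.000	0.000	0.465	0.412
GG	0.000	0.000	0.000	0.000	0.000	0.000	0.108	0.526
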