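Marker	Position	ObsHET	HWpval	MAF	Allele
rs2243191	01q32	0.406	0.8058	0.276	T:C
rs2856838	02q14	0.379	0.8236	0.249	C:T
rs583911	03q25	0.412	0.2625	0.268	G:A
rs2227306	04q13	0.476	0.3764	0.355	C:T
rs20541	05q31	0.426	0.9762	0.310	C:T
rs8193036	06p12	0.407	0.7335	0.293	C:T
rs4739139	08q12	0.445	0.0505	0.289	C:T
rs741344	12q15	0.465	0.4259	0.340	A:G
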