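transcript_id	name	length_kb	HR	C
hsa_circ_0084758	TRAM1	0.176	0.66	41.33
hsa_circ_0084756	TRAM1	0.383	0.81	21.56
hsa_circ_0084757	TRAM1	0.447	0.98	18.51
hsa_circ_0084759	TRAM1	0.422	3.08	20.04
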