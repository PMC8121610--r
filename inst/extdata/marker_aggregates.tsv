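transcript_id	HR	C	ECV304	RT4
CXCL8	382.32	93.83	111.86	181.13
RPS27	395.04	133.20	149.51	81.14
RPL23A	82.19	24.97	327.93	383.14
TRAM1	4.28	12.23	35.83	143.36
S100A6	90.06	21.49	1027.96	281.88
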