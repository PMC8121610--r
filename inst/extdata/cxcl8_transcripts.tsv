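transcript_id	name	length_kb	HR	C	tsl	biotype
ENST00000307407	CXCL8-201	1.705	618.357	148.984	1	retained_intron
ENST00000401931	CXCL8-202	0.700	365.908	86.693	1	protein_coding
ENST00000483500	CXCL8-203	0.599	162.685	45.813	2	protein_coding
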