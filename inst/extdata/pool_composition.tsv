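group	donor	KRT20	LASP1	OP18	UPK1A	BIRC5	rRNA_18S	mass_ng
C	48	1	1751	336	178	56	3320989	16
C	50	0	91	16	112	3	510671	18
C	80	32	1728	23	456	7	1009850	16
C	138	92	905	3	628	2	409198	13
C	160	3911	3081	2141	5109	151	1184859	16
C	166	8	363	27	204	1	193374	15
C	170	10	1338	36	79	2	607790	11
HR	41	7477	4758	2080	28110	446	12610137	18
HR	46	752	606	1850	13291	208	1803240	16
HR	107	91	3361	10	110	0	1452569	18
HR	128	9966	2388	777	5632	166	2329364	19
HR	159	1640	3350	325	5385	67	1585600	16
HR	164	3492	2507	411	3193	33	1538373	17
HR	183	42	5725	2756	1907	346	2816141	16
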