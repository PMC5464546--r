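accession	uniprot_id	gene	hazard_ratio	p_value
O43175	SERA_HUMAN	PHGDH	0.689	0.001
O75323	NIPS2_HUMAN	GBAS	1.830	0.001
P05091	ALDH2_HUMAN	ALDH2	0.423	0.002
P05161	ISG15_HUMAN	ISG15	0.500	0.002
P07996	TSP1_HUMAN	THBS1	0.649	0.002
P14317	HCLS1_HUMAN	HCLS1	0.379	0.003
P15153	RAC2_HUMAN	RAC2	0.423	0.003
P18085	ARF4_HUMAN	ARF4	3.754	0.003
P20340	RAB6A_HUMAN	RAB6A	0.493	0.004
P28065	PSB9_HUMAN	PSMB9	0.758	0.005
P53004	BIEA_HUMAN	BLVRA	0.674	0.006
P62873	GBB1_HUMAN	GNB1	0.703	0.006
Q09666	AHNK_HUMAN	AHNAK	1.614	0.006
Q15046	SYK_HUMAN	KARS	0.672	0.008
Q15181	IPYR_HUMAN	PPA1	2.184	0.008
Q9BUP0	EFHD1_HUMAN	EFHD1	0.265	0.009
Q9GZZ9	UBA5_HUMAN	UBA5	0.316	0.009
Q9NR31	SAR1A_HUMAN	SAR1A	0.222	0.009
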