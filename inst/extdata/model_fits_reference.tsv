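model	NP	LL	AIC_reported	N_CLI_0	N_CLII_0	N_CLI_1	N_CLII_1	N_ANC	T1_ka	T2_ka	Nm_I_II	Nm_II_I
1	7	-21333	98256	6030	3607	16757	4697	12835	6.4	8.8	NA	NA
2	9	-21240	97832	5008	1766	9429	7598	4480	2.6	490	1.777	2.141
3	9	-21246	97860	1982	1780	10000	5299	3907	0.4	532	2.235	2.387
4	9	-21243	97846	6032	3187	15412	100379	9658	18	89	2.528	1.901
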