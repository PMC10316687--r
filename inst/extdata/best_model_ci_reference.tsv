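parameter	mle	lo	hi
N_CLI_0	5008	3266	6873
N_CLII_0	1766	1185	2673
N_CLI_1	9429	7794	11432
N_CLII_1	7598	5581	10148
N_ANC	4480	1602	8036
T1_ka	2.6	1.3	5.1
T2_ka	490	292	671
Nm_I_II	1.777	1.437	2.202
Nm_II_I	2.141	1.744	2.353
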