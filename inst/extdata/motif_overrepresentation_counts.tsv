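comparison	tf	tf_class	ctrl_hits	ctrl_nonhits	target_hits	target_nonhits	z_printed	fisher_printed
background_validated_vs_background_nonresponding	RREB1	ZnF-C2H2	8	43	3	1	13.29	2.23E-02
background_validated_vs_background_nonresponding	Dl	REL	26	25	4	0	5.27	8.04E-02
background_validated_vs_background_nonresponding	NHLH1	bHLH	16	35	3	1	7.03	1.14E-01
nonbackground_validated_vs_nonbackground_nonresponding	MEF2A	MADS	116	92	13	2	4.48	1.55E-02
nonbackground_validated_vs_nonbackground_nonresponding	NHLH1	bHLH	120	88	12	3	7.98	7.36E-02
nonbackground_validated_vs_nonbackground_nonresponding	Fos	bZIP	181	27	15	0	4.10	1.35E-01
all_validated_vs_all_nonresponding	NHLH1	bHLH	136	123	15	4	9.79	2.07E-02
all_validated_vs_all_nonresponding	RREB1	ZnF-C2H2	50	209	8	11	11.49	2.49E-02
all_validated_vs_all_nonresponding	MEF2A	MADS	125	134	13	6	3.38	7.16E-02
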