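# units=nM
subject_id	genotype	flb_conc	ohf_conc	mr	oral_contraception	smoker
S0001	*1/*1	52888.1	54811.2	1.03636167682333	0	0
S0002	*1/*2	37129.4	38144.2	1.0273314408528	0	0
S0003	*1/*3	31486.4	21707.3	0.689418288530921	1	0
S0004	*2/*2	11128.3	11731.7	1.05422211838286	1	0
S0005	*2/*3	6521.7	3465.2	0.531333854669795	0	0
S0006	*3/*3	11212.2	2776.2	0.247605287097983	0	0
S0007	*1/*1	2527.4	2557	1.01171164042099	1	1
S0008	*1/*1	46151.1	65232.2	1.41344843351513	0	1
S0009	*1/*1	49433.8	46281.7	0.936235935736278	0	0
S0010	*2/*3	55595.5	26518.5	0.47699004415825	1	0
S0011	*1/*1	28752.5	35074	1.21985914268325	1	0
S0012	*3/*3	27466.7	6386.8	0.232528844018393	0	1
S0013	*1/*2	38231.3	36726.2	0.96063173368418	0	0
S0014	*1/*1	53518.9	76066	1.42129229113453	0	0
S0015	*1/*1	51485.7	63339.7	1.2302386876356	1	0
S0016	*1/*3	21654.6	15195.6	0.701726192125461	0	0
S0017	*1/*1	62012.7	66445.7	1.0714853570317	0	0
S0018	*1/*2	42534.9	46927.6	1.10327284183106	0	0
S0019	*1/*1	30120.2	27373	0.908792106294115	0	0
S0020	*1/*1	39532.7	75428.6	1.9080052715853	1	0
S0021	*1/*1	19263.6	20346.7	1.05622521231753	0	0
S0022	*1/*1	46675	66689.2	1.42879914301018	0	0
S0023	*1/*1	59806.6	76145	1.27318724020426	0	0
S0024	*1/*2	43935.1	50781.8	1.15583667728081	0	1
S0025	*1/*1	12697.8	11931	0.939611586259037	0	0
S0026	*1/*3	23054.5	13837.3	0.60019952720727	1	0
S0027	*1/*1	8710.4	8438.6	0.968795922116091	1	1
S0028	*1/*2	7726.5	8091.4	1.04722707564874	1	0
S0029	*1/*2	19853.3	15271.6	0.76922224516831	0	0
S0030	*1/*1	54364.2	68965	1.26857380408431	0	0
S0031	*1/*3	64238.2	44092.5	0.686390652291004	1	0
S0032	*1/*1	28744.1	49918.4	1.73664856440104	1	1
S0033	*1/*2	13759.8	13393.6	0.973386241079086	0	0
S0034	*1/*2	62392.1	61065.6	0.978739295519785	0	0
S0035	*1/*1	43005.5	42065.9	0.97815163176803	1	0
S0036	*1/*1	19863.7	22312.1	1.12326001701596	0	1
S0037	*1/*1	8438.5	10537	1.24868163773182	1	1
S0038	*1/*2	39132.1	42440.7	1.08454951305961	1	1
S0039	*1/*1	8497.8	12935.2	1.5221822118666	0	0
S0040	*1/*3	51185	48613.3	0.949756764677152	1	0
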