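feature_id	gene	TH	THC	PC	P
Cluster-28098.16	1433D_SOYBN	277.4	291.9	0.2	0.0
Cluster-30463.1	ACT11_ARATH	0.3	5.2	1.7	0.0
Cluster-30642.1	ACT1_ORYSI	0.3	1.2	7.2	0.1
Cluster-26673.1	AMT11_SOLLC	234.2	428.8	2.1	0.0
Cluster-37206.1	CAF1K_ARATH	294.3	412.9	0.2	0.0
Cluster-28144.0	CAES_ARATH	34.6	179.0	1.2	0.0
Cluster-40689.0	CHIT_PERAE	82.1	604.1	2.2	0.0
Cluster-2905.1	ALPL_ARATH	243.2	350.0	2.6	0.0
Cluster-33686.3	dehydrin	3321	6625	4.0	0.1
Cluster-25215.6	EP1L4_ARATH	499.1	735.5	1.1	0.0
Cluster-28520.1	DUF4228	309.4	405.8	0.3	0.0
Cluster-31749.0	DUF4723	50.4	604.3	2.0	0.1
Cluster-28199.1	ESSS	475.7	553.4	0.6	0.0
Cluster-86868.1	ERM	0.0	0.1	0.1	0.0
Cluster-28808.1	BBE21_ARATH	80.6	336.6	1.5	0.0
Cluster-31390.0	CASL1_CANSA	88.5	126.5	1.7	0.0
Cluster-24876.1	DUF716	15.3	18.8	0.7	0.0
Cluster-26009.1	FB119_ARATH	34.9	118.7	0.2	0.0
Cluster-20986.5	GSTF_HYOMU	249.2	502.4	1.3	0.0
Cluster-20103.7	GADPH	395	576.7	0.8	0.0
Cluster-23641.1	XTH23_ARATH	460.3	981.2	3.8	0.0
Cluster-26468.1	ERLL1_ARATH	136.7	490.7	0.1	0.0
Cluster-29998.1	LEA14_GOSHI	425.5	842.2	0.2	0.0
Cluster-28203.4	GILP_ARATH	67.1	80.9	0.1	0.0
Cluster-27980.8	FPPS1_LUPAL	43.3	217.8	0.2	0.0
Cluster-29223.2	MSK3_MEDSA	204.5	265.7	1.2	0.0
Cluster-26011.1	CRK7_ARATH	37.4	46.4	0.5	0.0
Cluster-15047.1	SPE1_PEA	489.5	618.4	1.0	0.0
Cluster-25493.2	RL72_ARATH	323.6	331.5	0.3	0.0
Cluster-28869.1	RL72_ARATH_2	139.9	210.5	0.1	0.0
Cluster-27350.3	RL3_ORYSJ	1144	1163	0.7	0.0
Cluster-25988.1	RL262_ARATH	382.7	481.3	0.3	0.0
Cluster-29252.2	RICI_RICCO	765.1	2370	1.4	0.0
Cluster-29448.5	CSE_ARATH	6.9	43.7	0.0	0.0
Cluster-72533.2	STC	0.1	0.5	1.0	0.9
Cluster-37697.0	TCTP_ELAGV	8295	9521	5.7	0.1
Cluster-25717.1	SSRA_ARATH	89.6	106.1	0.9	0.0
Cluster-27790.5	LHT1_ARATH	32.4	138.4	0.9	0.0
Cluster-30943.0	TBA_EUGGR	0.1	0.5	2.2	0.0
Cluster-43188.0	TBB_CHLIN	0.4	1.7	4.4	0.1
Cluster-26035.2	U73D1_ARATH	53.1	120.9	0.2	0.0
Cluster-44341.8	ZFP	0.0	0.1	0.3	0.0
Cluster-27579.1	EXLB1_ARATH	294.2	1724	1.2	0.0
Cluster-92147.2	ARI4_ARATH	0.1	0.1	0.7	0.1
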