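index	abbrev	module
1	Tpole.R	temporal
2	BA19.R	visual
3	BA19.L	visual
4	PHP.L	temporal
5	OFC.R	prefrontal
6	IFG.L	prefrontal
7	MPFC	prefrontal
8	IPUT.R	subcortical
9	BA21	temporal
10	VIS.L	visual
11	PUT.L	subcortical
12	DPUT.R	subcortical
13	INS.L	temporal
14	LPFC.R	prefrontal
15	MFC	prefrontal
16	LPFC.L	prefrontal
17	BA19.L	visual
18	BA40.R	parietal
19	PFC.R	prefrontal
20	PCC	parietal
21	SEN.L	parietal
22	SPFC.L	prefrontal
23	ACC	prefrontal
24	BA39.L	parietal
25	SEN.R	parietal
26	TPJ.L	parietal
27	STG.L	temporal
28	MTG.R	temporal
29	ITG.L	temporal
30	SFG.R	prefrontal
31	IPL.L	parietal
32	SMA	prefrontal
33	PCC	parietal
34	PUT.L	subcortical
35	VIS.R	visual
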