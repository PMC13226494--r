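query_id	subject_id	bit_score	family_hint	genome
TCDB_2.A.1.1.x	AEW03687.1	337	MFS	S_acidophilus
TCDB_2.A.1.1.x	AEW03843.1	374	MFS	S_acidophilus
TCDB_2.A.1.1.x	AEW04311.1	411	MFS	S_acidophilus
TCDB_2.A.1.1.x	AEW04366.1	448	MFS	S_acidophilus
TCDB_2.A.1.1.x	AEW04492.1	305	MFS	S_acidophilus
TCDB_2.A.1.1.x	AEW06192.1	342	MFS	S_acidophilus
TCDB_2.A.1.1.x	AEW06836.1	379	MFS	S_acidophilus
TCDB_2.A.1.1.x	AEW06866.1	416	MFS	S_acidophilus
TCDB_2.A.1.1.x	SMC02092.1	347	MFS	S_thermosulfidooxidans
TCDB_2.A.1.1.x	SMC03406.1	384	MFS	S_thermosulfidooxidans
TCDB_2.A.1.1.x	SMC03458.1	421	MFS	S_thermosulfidooxidans
TCDB_2.A.1.1.x	SMC03679.1	458	MFS	S_thermosulfidooxidans
TCDB_2.A.1.1.x	SMC04707.1	315	MFS	S_thermosulfidooxidans
TCDB_2.A.1.1.x	SMC06847.1	352	MFS	S_thermosulfidooxidans
TCDB_2.A.1.1.x	SMC07961.1	389	MFS	S_thermosulfidooxidans
TCDB_2.A.1.1.x	SMC08103.1	426	MFS	S_thermosulfidooxidans
TCDB_2.A.39.x	AEW03658.1	257	NCS1	S_acidophilus
TCDB_2.A.39.x	AEW03975.1	294	NCS1	S_acidophilus
TCDB_2.A.39.x	AEW04998.1	331	NCS1	S_acidophilus
TCDB_2.A.39.x	AEW05769.1	368	NCS1	S_acidophilus
TCDB_2.A.39.x	AEW05778.1	225	NCS1	S_acidophilus
TCDB_2.A.39.x	AEW05805.1	262	NCS1	S_acidophilus
TCDB_2.A.39.x	AEW06333.1	299	NCS1	S_acidophilus
TCDB_2.A.39.x	SMC03286.1	267	NCS1	S_thermosulfidooxidans
TCDB_2.A.39.x	SMC03685.1	304	NCS1	S_thermosulfidooxidans
TCDB_2.A.39.x	SMC04878.1	341	NCS1	S_thermosulfidooxidans
TCDB_2.A.39.x	SMC05746.1	378	NCS1	S_thermosulfidooxidans
TCDB_2.A.39.x	SMC05151.1	235	NCS1	S_thermosulfidooxidans
TCDB_2.A.39.x	SMC05779.1	272	NCS1	S_thermosulfidooxidans
TCDB_2.A.39.x	SMC05783.1	309	NCS1	S_thermosulfidooxidans
TCDB_2.A.39.x	SMC06926.1	346	NCS1	S_thermosulfidooxidans
TCDB_2.A.39.x	SMC06946.1	383	NCS1	S_thermosulfidooxidans
TCDB_2.A.39.x	SMC07038.1	240	NCS1	S_thermosulfidooxidans
TCDB_2.A.1.1.x	AEW07777.1	95	MFS	S_acidophilus
TCDB_2.A.1.1.x	SMC07777.1	100	MFS	S_thermosulfidooxidans
TCDB_2.A.1.1.x	AEW07778.1	450	MFS	S_acidophilus
TCDB_2.A.39.x	SMC07778.1	300	NCS1	S_thermosulfidooxidans
TCDB_4.A.5.x	SMC09101.1	210	PTS	S_thermosulfidooxidans
TCDB_4.A.5.x	SMC09102.1	185	PTS	S_thermosulfidooxidans
TCDB_4.A.5.x	SMC09103.1	160	PTS	S_thermosulfidooxidans
TCDB_3.A.1.1.x	AEW06695.1	332	ABC_SBP	S_acidophilus
TCDB_3.A.1.1.x	AEW06696.1	333	ABC_TM	S_acidophilus
TCDB_3.A.1.1.x	AEW06697.1	334	ABC_TM	S_acidophilus
TCDB_3.A.1.1.x	AEW05613.1	307	ABC_SBP	S_acidophilus
TCDB_3.A.1.1.x	AEW05614.1	308	ABC_TM	S_acidophilus
TCDB_3.A.1.1.x	AEW05615.1	309	ABC_TM	S_acidophilus
TCDB_3.A.1.1.x	AEW05654.1	310	ABC_SBP	S_acidophilus
TCDB_3.A.1.1.x	AEW05655.1	311	ABC_TM	S_acidophilus
TCDB_3.A.1.1.x	AEW05656.1	312	ABC_TM	S_acidophilus
TCDB_3.A.1.1.x	AEW05692.1	303	ABC_SBP	S_acidophilus
TCDB_3.A.1.1.x	AEW05693.1	304	ABC_TM	S_acidophilus
TCDB_3.A.1.1.x	AEW05694.1	305	ABC_TM	S_acidophilus
TCDB_3.A.1.1.x	AEW05739.1	306	ABC_SBP	S_acidophilus
TCDB_3.A.1.1.x	AEW05740.1	307	ABC_TM	S_acidophilus
TCDB_3.A.1.1.x	AEW05741.1	308	ABC_TM	S_acidophilus
TCDB_3.A.1.1.x	SMC02421.1	339	ABC_SBP	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC02424.1	340	ABC_TM	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC02425.1	341	ABC_TM	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC02096.1	336	ABC_SBP	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC02097.1	337	ABC_TM	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC02098.1	338	ABC_TM	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC03611.1	342	ABC_SBP	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC03613.1	343	ABC_TM	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC03615.1	344	ABC_TM	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC04071.1	335	ABC_SBP	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC04073.1	336	ABC_TM	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC04077.1	337	ABC_TM	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC08218.1	345	ABC_SBP	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC08219.1	346	ABC_TM	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC08220.1	347	ABC_TM	S_thermosulfidooxidans
TCDB_3.A.1.1.x	AEW05601.1	304	ABC_NBP	S_acidophilus
TCDB_3.A.1.1.x	AEW05602.1	305	ABC_SBP	S_acidophilus
TCDB_3.A.1.1.x	AEW05603.1	306	ABC_TM	S_acidophilus
TCDB_3.A.1.1.x	AEW06309.1	322	ABC_NBP	S_acidophilus
TCDB_3.A.1.1.x	AEW06310.1	323	ABC_SBP	S_acidophilus
TCDB_3.A.1.1.x	AEW06311.1	324	ABC_TM	S_acidophilus
TCDB_3.A.1.1.x	AEW06312.1	325	ABC_SBP	S_acidophilus
TCDB_3.A.1.1.x	AEW05664.1	300	ABC_NBP	S_acidophilus
TCDB_3.A.1.1.x	AEW05665.1	301	ABC_SBP	S_acidophilus
TCDB_3.A.1.1.x	AEW05666.1	302	ABC_TM	S_acidophilus
TCDB_3.A.1.1.x	SMC03773.1	345	ABC_NBP	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC03777.1	346	ABC_SBP	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC03779.1	347	ABC_TM	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC05763.1	354	ABC_NBP	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC05769.1	355	ABC_SBP	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC05771.1	356	ABC_TM	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC05772.1	357	ABC_SBP	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC04677.1	338	ABC_NBP	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC04682.1	339	ABC_SBP	S_thermosulfidooxidans
TCDB_3.A.1.1.x	SMC04684.1	340	ABC_TM	S_thermosulfidooxidans
TCDB_4.A.2.x	AEW06621.1	313	PTS	S_acidophilus
TCDB_4.A.2.x	AEW06622.1	314	PTS	S_acidophilus
TCDB_4.A.2.x	AEW06623.1	315	PTS	S_acidophilus
TCDB_4.A.2.x	AEW06624.1	316	PTS	S_acidophilus
TCDB_4.A.2.x	AEW06625.1	317	PTS	S_acidophilus
TCDB_4.A.2.x	AEW06626.1	318	PTS	S_acidophilus
TCDB_3.A.1.1.x	AEW09001.1	361	ABC_NBP	S_acidophilus
TCDB_3.A.1.1.x	SMC09001.1	387	ABC_NBP	S_thermosulfidooxidans
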