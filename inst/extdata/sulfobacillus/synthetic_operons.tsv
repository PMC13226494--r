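operon_id	seq_id	role	genome	substrate
sa_cut1_glc	AEW06695.1	SBP	S_acidophilus	glucose/mannose
sa_cut1_glc	AEW06696.1	TM	S_acidophilus	glucose/mannose
sa_cut1_glc	AEW06697.1	TM	S_acidophilus	glucose/mannose
sa_cut1_xyl	AEW05613.1	SBP	S_acidophilus	xylose
sa_cut1_xyl	AEW05614.1	TM	S_acidophilus	xylose
sa_cut1_xyl	AEW05615.1	TM	S_acidophilus	xylose
sa_cut1_tre	AEW05654.1	SBP	S_acidophilus	trehalose
sa_cut1_tre	AEW05655.1	TM	S_acidophilus	trehalose
sa_cut1_tre	AEW05656.1	TM	S_acidophilus	trehalose
sa_cut1_u1	AEW05692.1	SBP	S_acidophilus	NA
sa_cut1_u1	AEW05693.1	TM	S_acidophilus	NA
sa_cut1_u1	AEW05694.1	TM	S_acidophilus	NA
sa_cut1_u2	AEW05739.1	SBP	S_acidophilus	NA
sa_cut1_u2	AEW05740.1	TM	S_acidophilus	NA
sa_cut1_u2	AEW05741.1	TM	S_acidophilus	NA
st_cut1_glc	SMC02421.1	SBP	S_thermosulfidooxidans	glucose/mannose
st_cut1_glc	SMC02424.1	TM	S_thermosulfidooxidans	glucose/mannose
st_cut1_glc	SMC02425.1	TM	S_thermosulfidooxidans	glucose/mannose
st_cut1_gly	SMC02096.1	SBP	S_thermosulfidooxidans	glycerol
st_cut1_gly	SMC02097.1	TM	S_thermosulfidooxidans	glycerol
st_cut1_gly	SMC02098.1	TM	S_thermosulfidooxidans	glycerol
st_cut1_gos	SMC03611.1	SBP	S_thermosulfidooxidans	galactooligosaccharides
st_cut1_gos	SMC03613.1	TM	S_thermosulfidooxidans	galactooligosaccharides
st_cut1_gos	SMC03615.1	TM	S_thermosulfidooxidans	galactooligosaccharides
st_cut1_u1	SMC04071.1	SBP	S_thermosulfidooxidans	NA
st_cut1_u1	SMC04073.1	TM	S_thermosulfidooxidans	NA
st_cut1_u1	SMC04077.1	TM	S_thermosulfidooxidans	NA
st_cut1_u2	SMC08218.1	SBP	S_thermosulfidooxidans	NA
st_cut1_u2	SMC08219.1	TM	S_thermosulfidooxidans	NA
st_cut1_u2	SMC08220.1	TM	S_thermosulfidooxidans	NA
sa_cut2_rib	AEW05601.1	NBP	S_acidophilus	ribose
sa_cut2_rib	AEW05602.1	SBP	S_acidophilus	ribose
sa_cut2_rib	AEW05603.1	TM	S_acidophilus	ribose
sa_cut2_nuc	AEW06309.1	NBP	S_acidophilus	nucleosides
sa_cut2_nuc	AEW06310.1	SBP	S_acidophilus	nucleosides
sa_cut2_nuc	AEW06311.1	TM	S_acidophilus	nucleosides
sa_cut2_nuc	AEW06312.1	SBP	S_acidophilus	nucleosides
sa_cut2_u1	AEW05664.1	NBP	S_acidophilus	NA
sa_cut2_u1	AEW05665.1	SBP	S_acidophilus	NA
sa_cut2_u1	AEW05666.1	TM	S_acidophilus	NA
st_cut2_rib	SMC03773.1	NBP	S_thermosulfidooxidans	ribose
st_cut2_rib	SMC03777.1	SBP	S_thermosulfidooxidans	ribose
st_cut2_rib	SMC03779.1	TM	S_thermosulfidooxidans	ribose
st_cut2_nuc	SMC05763.1	NBP	S_thermosulfidooxidans	nucleosides
st_cut2_nuc	SMC05769.1	SBP	S_thermosulfidooxidans	nucleosides
st_cut2_nuc	SMC05771.1	TM	S_thermosulfidooxidans	nucleosides
st_cut2_nuc	SMC05772.1	SBP	S_thermosulfidooxidans	nucleosides
st_cut2_u1	SMC04677.1	NBP	S_thermosulfidooxidans	NA
st_cut2_u1	SMC04682.1	SBP	S_thermosulfidooxidans	NA
st_cut2_u1	SMC04684.1	TM	S_thermosulfidooxidans	NA
sa_pts_fru	AEW06621.1	EII	S_acidophilus	fructose
sa_pts_fru	AEW06622.1	EII	S_acidophilus	fructose
sa_pts_fru	AEW06623.1	EII	S_acidophilus	fructose
sa_pts_fru	AEW06624.1	EII	S_acidophilus	fructose
sa_pts_fru	AEW06625.1	EII	S_acidophilus	fructose
sa_pts_fru	AEW06626.1	EII	S_acidophilus	fructose
sa_nbp_shared	AEW09001.1	NBP	S_acidophilus	NA
st_nbp_shared	SMC09001.1	NBP	S_thermosulfidooxidans	NA
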