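seq_id	tm_helix_count	has_signal_peptide	length_aa
AEW03687.1	12	FALSE	447
AEW03843.1	12	FALSE	454
AEW04311.1	12	FALSE	461
AEW04366.1	12	FALSE	468
AEW04492.1	12	FALSE	475
AEW06192.1	12	FALSE	482
AEW06836.1	12	FALSE	489
AEW06866.1	12	FALSE	496
SMC02092.1	12	FALSE	443
SMC03406.1	12	FALSE	450
SMC03458.1	12	FALSE	457
SMC03679.1	12	FALSE	464
SMC04707.1	12	FALSE	471
SMC06847.1	12	FALSE	478
SMC07961.1	12	FALSE	485
SMC08103.1	12	FALSE	492
AEW03658.1	12	FALSE	441
AEW03975.1	12	FALSE	452
AEW04998.1	12	FALSE	463
AEW05769.1	12	FALSE	474
AEW05778.1	12	FALSE	435
AEW05805.1	12	FALSE	446
AEW06333.1	12	FALSE	457
SMC03286.1	12	FALSE	468
SMC03685.1	12	FALSE	479
SMC04878.1	12	FALSE	440
SMC05746.1	12	FALSE	451
SMC05151.1	12	FALSE	462
SMC05779.1	12	FALSE	473
SMC05783.1	12	FALSE	434
SMC06926.1	12	FALSE	445
SMC06946.1	12	FALSE	456
SMC07038.1	12	FALSE	467
AEW07777.1	12	FALSE	445
SMC07777.1	12	FALSE	445
AEW07778.1	11	FALSE	432
SMC07778.1	13	FALSE	428
AEW06695.1	1	TRUE	420
AEW06696.1	6	FALSE	300
AEW06697.1	6	FALSE	300
AEW05613.1	1	TRUE	420
AEW05614.1	6	FALSE	300
AEW05615.1	6	FALSE	300
AEW05654.1	1	TRUE	420
AEW05655.1	6	FALSE	300
AEW05656.1	6	FALSE	300
AEW05692.1	1	TRUE	420
AEW05693.1	6	FALSE	300
AEW05694.1	6	FALSE	300
AEW05739.1	1	TRUE	420
AEW05740.1	6	FALSE	300
AEW05741.1	6	FALSE	300
SMC02421.1	1	TRUE	420
SMC02424.1	6	FALSE	300
SMC02425.1	6	FALSE	300
SMC02096.1	1	TRUE	420
SMC02097.1	6	FALSE	300
SMC02098.1	6	FALSE	300
SMC03611.1	1	TRUE	420
SMC03613.1	6	FALSE	300
SMC03615.1	6	FALSE	300
SMC04071.1	1	TRUE	420
SMC04073.1	6	FALSE	300
SMC04077.1	6	FALSE	300
SMC08218.1	1	TRUE	420
SMC08219.1	6	FALSE	300
SMC08220.1	6	FALSE	300
AEW05601.1	0	FALSE	360
AEW05602.1	1	TRUE	420
AEW05603.1	6	FALSE	300
AEW06309.1	0	FALSE	360
AEW06310.1	1	TRUE	420
AEW06311.1	6	FALSE	300
AEW06312.1	1	TRUE	420
AEW05664.1	0	FALSE	360
AEW05665.1	1	TRUE	420
AEW05666.1	6	FALSE	300
SMC03773.1	0	FALSE	360
SMC03777.1	1	TRUE	420
SMC03779.1	6	FALSE	300
SMC05763.1	0	FALSE	360
SMC05769.1	1	TRUE	420
SMC05771.1	6	FALSE	300
SMC05772.1	1	TRUE	420
SMC04677.1	0	FALSE	360
SMC04682.1	1	TRUE	420
SMC04684.1	6	FALSE	300
AEW09001.1	0	FALSE	360
SMC09001.1	0	FALSE	360
AEW06621.1	0	FALSE	150
AEW06622.1	0	FALSE	170
AEW06623.1	8	FALSE	460
AEW06624.1	0	FALSE	130
AEW06625.1	2	FALSE	210
AEW06626.1	0	FALSE	330
SMC09101.1	0	FALSE	330
SMC09102.1	0	FALSE	210
SMC09103.1	0	FALSE	90
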