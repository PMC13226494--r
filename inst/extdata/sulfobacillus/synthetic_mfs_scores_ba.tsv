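query_id	subject_id	bit_score
SMC02092.1	AEW03687.1	50
SMC02092.1	AEW03843.1	53
SMC02092.1	AEW04311.1	56
SMC02092.1	AEW04366.1	59
SMC02092.1	AEW04492.1	62
SMC02092.1	AEW06192.1	501
SMC02092.1	AEW06836.1	43
SMC02092.1	AEW06866.1	46
SMC03406.1	AEW03687.1	57
SMC03406.1	AEW03843.1	60
SMC03406.1	AEW04311.1	63
SMC03406.1	AEW04366.1	200
SMC03406.1	AEW04492.1	44
SMC03406.1	AEW06192.1	47
SMC03406.1	AEW06836.1	50
SMC03406.1	AEW06866.1	53
SMC03458.1	AEW03687.1	64
SMC03458.1	AEW03843.1	42
SMC03458.1	AEW04311.1	45
SMC03458.1	AEW04366.1	48
SMC03458.1	AEW04492.1	51
SMC03458.1	AEW06192.1	54
SMC03458.1	AEW06836.1	57
SMC03458.1	AEW06866.1	503
SMC03679.1	AEW03687.1	46
SMC03679.1	AEW03843.1	49
SMC03679.1	AEW04311.1	52
SMC03679.1	AEW04366.1	504
SMC03679.1	AEW04492.1	58
SMC03679.1	AEW06192.1	61
SMC03679.1	AEW06836.1	64
SMC03679.1	AEW06866.1	42
SMC04707.1	AEW03687.1	53
SMC04707.1	AEW03843.1	56
SMC04707.1	AEW04311.1	59
SMC04707.1	AEW04366.1	200
SMC04707.1	AEW04492.1	40
SMC04707.1	AEW06192.1	43
SMC04707.1	AEW06836.1	46
SMC04707.1	AEW06866.1	49
SMC06847.1	AEW03687.1	60
SMC06847.1	AEW03843.1	63
SMC06847.1	AEW04311.1	41
SMC06847.1	AEW04366.1	200
SMC06847.1	AEW04492.1	47
SMC06847.1	AEW06192.1	50
SMC06847.1	AEW06836.1	53
SMC06847.1	AEW06866.1	56
SMC07961.1	AEW03687.1	42
SMC07961.1	AEW03843.1	45
SMC07961.1	AEW04311.1	48
SMC07961.1	AEW04366.1	200
SMC07961.1	AEW04492.1	54
SMC07961.1	AEW06192.1	57
SMC07961.1	AEW06836.1	60
SMC07961.1	AEW06866.1	63
SMC08103.1	AEW03687.1	49
SMC08103.1	AEW03843.1	52
SMC08103.1	AEW04311.1	55
SMC08103.1	AEW04366.1	58
SMC08103.1	AEW04492.1	61
SMC08103.1	AEW06192.1	64
SMC08103.1	AEW06836.1	508
SMC08103.1	AEW06866.1	45
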