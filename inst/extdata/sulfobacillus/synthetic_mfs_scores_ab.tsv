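query_id	subject_id	bit_score
AEW03687.1	SMC02092.1	50
AEW03687.1	SMC03406.1	53
AEW03687.1	SMC03458.1	56
AEW03687.1	SMC03679.1	200
AEW03687.1	SMC04707.1	62
AEW03687.1	SMC06847.1	40
AEW03687.1	SMC07961.1	43
AEW03687.1	SMC08103.1	46
AEW03843.1	SMC02092.1	57
AEW03843.1	SMC03406.1	60
AEW03843.1	SMC03458.1	63
AEW03843.1	SMC03679.1	200
AEW03843.1	SMC04707.1	44
AEW03843.1	SMC06847.1	47
AEW03843.1	SMC07961.1	50
AEW03843.1	SMC08103.1	53
AEW04311.1	SMC02092.1	64
AEW04311.1	SMC03406.1	200
AEW04311.1	SMC03458.1	45
AEW04311.1	SMC03679.1	200
AEW04311.1	SMC04707.1	51
AEW04311.1	SMC06847.1	54
AEW04311.1	SMC07961.1	57
AEW04311.1	SMC08103.1	60
AEW04366.1	SMC02092.1	46
AEW04366.1	SMC03406.1	49
AEW04366.1	SMC03458.1	52
AEW04366.1	SMC03679.1	504
AEW04366.1	SMC04707.1	58
AEW04366.1	SMC06847.1	61
AEW04366.1	SMC07961.1	64
AEW04366.1	SMC08103.1	42
AEW04492.1	SMC02092.1	53
AEW04492.1	SMC03406.1	56
AEW04492.1	SMC03458.1	59
AEW04492.1	SMC03679.1	200
AEW04492.1	SMC04707.1	40
AEW04492.1	SMC06847.1	43
AEW04492.1	SMC07961.1	46
AEW04492.1	SMC08103.1	49
AEW06192.1	SMC02092.1	506
AEW06192.1	SMC03406.1	63
AEW06192.1	SMC03458.1	41
AEW06192.1	SMC03679.1	44
AEW06192.1	SMC04707.1	47
AEW06192.1	SMC06847.1	50
AEW06192.1	SMC07961.1	53
AEW06192.1	SMC08103.1	56
AEW06836.1	SMC02092.1	42
AEW06836.1	SMC03406.1	45
AEW06836.1	SMC03458.1	48
AEW06836.1	SMC03679.1	51
AEW06836.1	SMC04707.1	54
AEW06836.1	SMC06847.1	57
AEW06836.1	SMC07961.1	60
AEW06836.1	SMC08103.1	507
AEW06866.1	SMC02092.1	49
AEW06866.1	SMC03406.1	52
AEW06866.1	SMC03458.1	508
AEW06866.1	SMC03679.1	58
AEW06866.1	SMC04707.1	61
AEW06866.1	SMC06847.1	64
AEW06866.1	SMC07961.1	42
AEW06866.1	SMC08103.1	45
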