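category	icd_version	code
CVD	9	3361
CVD	9	36231
CVD	9	36232
CVD	9	39-44
CVD	10	I00-I78
CVD	10	G951
CVD	10	H431
CVD	10	H432
CVD	10	H341
CVD	10	H342
CVD	10	O10
CVD	10	S066
CVD	10	Z951
CVD	10	Z955
CHD	9	410
CHD	9	412
CHD	9	414
CHD	10	I21-25
CHD	10	Z951
CHD	10	Z955
MI	9	410
MI	9	412
MI	10	I21-I23
MI	10	I252
HF	9	428
HF	10	I110
HF	10	I130
HF	10	I132
HF	10	I50
hypertension	9	401-405
hypertension	10	I10-I13
hypertension	10	I15
hypertension	10	O10
stroke	9	3361
stroke	9	36231
stroke	9	36232
stroke	9	430
stroke	9	431
stroke	9	4329
stroke	9	43301
stroke	9	43311
stroke	9	43331
stroke	9	43381
stroke	9	43391
stroke	9	434
stroke	9	436
stroke	10	I60
stroke	10	I61
stroke	10	I629
stroke	10	I63
stroke	10	I64
stroke	10	I678
stroke	10	I690
stroke	10	I693
stroke	10	G951
stroke	10	H341
stroke	10	H342
stroke	10	S066
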