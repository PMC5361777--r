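family	count
I1	61
I2	527
I4	287
I8	237
I21	3
I25	102
I29	39
I31	53
I32	12
I35	6
I39	63
I43	75
I51	31
I53	10
I63	62
I68	24
I72	2
I74	1
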