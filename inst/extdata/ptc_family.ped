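PTC1	S1	0	0	1	2	exclude
PTC1	S2	0	0	2	2
PTC1	S3	0	0	2	2
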