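stage	W	N1	N2	N3	REM
W	7844	276	87	14	68
N1	387	1131	614	12	405
N2	109	241	14858	514	459
N3	17	0	461	4706	1
REM	106	257	582	2	6068
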