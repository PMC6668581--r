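id	score	cleavage	call
pla_0001	0.91	20	SP
pla_0002	0.88	24	SP
sec_0001	0.79	18	SP
mit_0001	0.12		mTP
cyt_0001	0.03		other
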