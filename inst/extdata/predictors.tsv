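predictor	proteins
P1	P53004;P05161;P28065;O75323
P5	P53004;P20340;P15153;Q15181
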