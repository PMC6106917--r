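band,score_min,score_max,n
none,0,12,112
perceived,13,45,96
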