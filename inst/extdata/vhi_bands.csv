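band,score_min,score_max,n
none,0,32,155
mild,33,43,19
moderate,44,60,16
severe,61,180,18
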