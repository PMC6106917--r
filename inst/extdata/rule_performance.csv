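parameter,system,accuracy,sensitivity,specificity
f0,mhealth_app,54.3,53.3,56.9
f0,praat,50.0,44.0,65.5
jitter,mhealth_app,72.6,96.0,12.1
jitter,praat,40.4,20.0,93.1
shimmer,mhealth_app,72.6,89.3,29.3
shimmer,praat,57.7,58.7,55.2
hnr,mhealth_app,61.1,64.7,51.7
hnr,praat,63.0,71.3,41.4
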