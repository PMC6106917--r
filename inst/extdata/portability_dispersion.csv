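voice_id,parameter,devst_printed,anomaly
voice_003,f0,23.3,
voice_003,jitter,0.05,
voice_003,shimmer,0.05,
voice_003,hnr,2.03,
voice_026,f0,23.25,
voice_026,jitter,0.01,
voice_026,shimmer,0.01,true
voice_026,hnr,0.87,
voice_041,f0,16.32,
voice_041,jitter,0.01,
voice_041,shimmer,0.01,
voice_041,hnr,1.60,
voice_047,f0,16.90,
voice_047,jitter,0.01,
voice_047,shimmer,0.02,
voice_047,hnr,1.83,
voice_055,f0,15.09,
voice_055,jitter,0.06,
voice_055,shimmer,0.02,
voice_055,hnr,1.89,
voice_084,f0,12.74,
voice_084,jitter,0.01,
voice_084,shimmer,0.02,
voice_084,hnr,2.56,
voice_086,f0,10.94,
voice_086,jitter,0.07,
voice_086,shimmer,0.03,
voice_086,hnr,1.58,
voice_102,f0,14.97,
voice_102,jitter,0.02,
voice_102,shimmer,0.02,
voice_102,hnr,1.63,
voice_202,f0,7.89,
voice_202,jitter,0.04,
voice_202,shimmer,0.02,
voice_202,hnr,1.37,
voice_208,f0,19.66,
voice_208,jitter,0.03,
voice_208,shimmer,0.02,
voice_208,hnr,1.72,
voice_045,f0,18.55,
voice_045,jitter,0.04,
voice_045,shimmer,0.02,
voice_045,hnr,0.76,
voice_095,f0,33.32,
voice_095,jitter,0.02,
voice_095,shimmer,0.04,
voice_095,hnr,1.78,
voice_097,f0,9.11,
voice_097,jitter,0.02,
voice_097,shimmer,0.04,
voice_097,hnr,2.02,
voice_100,f0,16.75,
voice_100,jitter,0.03,
voice_100,shimmer,0.03,
voice_100,hnr,3.18,
voice_104,f0,14.48,
voice_104,jitter,0.01,
voice_104,shimmer,0.02,
voice_104,hnr,1.15,
voice_107,f0,13.77,
voice_107,jitter,0.02,
voice_107,shimmer,0.05,
voice_107,hnr,0.65,
voice_109,f0,19.62,
voice_109,jitter,0.01,
voice_109,shimmer,0.04,
voice_109,hnr,1.70,
voice_123,f0,16.27,
voice_123,jitter,0.01,
voice_123,shimmer,0.03,
voice_123,hnr,1.23,
voice_158,f0,14.93,
voice_158,jitter,0.03,
voice_158,shimmer,0.03,
voice_158,hnr,0.84,
voice_180,f0,14.91,
voice_180,jitter,0.03,
voice_180,shimmer,0.02,true
voice_180,hnr,0.97,
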