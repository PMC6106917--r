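voice_id,recording,gender,clinician_label,note,f0,f0_verdict,jitter,jitter_verdict,shimmer,shimmer_verdict,hnr,hnr_verdict,anomaly
voice_061,1,female,healthy,,217,healthy,1.323,pathological,1.520,pathological,24.36,healthy,
voice_061,2,female,healthy,,211,healthy,1.323,pathological,1.518,pathological,26.985,healthy,
voice_076,1,female,pathological,corrupted_too_short,212,healthy,1.306,pathological,2.565,pathological,4.302,pathological,
voice_076,2,female,pathological,corrupted_too_short,320,pathological,1.318,pathological,2.344,pathological,7.738,pathological,
voice_089,1,female,pathological,,148,pathological,1.140,pathological,1.392,pathological,0.457,pathological,
voice_089,2,female,pathological,,154,pathological,1.322,pathological,2.503,pathological,1.915,pathological,
voice_108,1,male,healthy,corrupted_speech,188,pathological,1.003,healthy,0.024,healthy,24.749,healthy,
voice_108,2,male,healthy,corrupted_speech,153,healthy,1.323,pathological,3.045,pathological,8.486,pathological,
voice_125,1,female,pathological,,40,pathological,0.937,healthy,2.093,pathological,15.906,pathological,
voice_125,2,female,pathological,,41,pathological,0.759,healthy,2.744,pathological,10.898,pathological,
voice_128,1,male,pathological,,175,pathological,1.305,pathological,4.214,pathological,5.465,pathological,
voice_128,2,male,pathological,,160,pathological,1.363,pathological,1.885,pathological,5.125,pathological,
voice_138,1,male,pathological,,251,pathological,1.306,pathological,1.747,pathological,11.995,pathological,
voice_138,2,male,pathological,,229,pathological,1.306,pathological,1.733,pathological,10.626,pathological,
voice_146,1,female,healthy,,145,pathological,0.878,healthy,0.025,healthy,6.048,pathological,
voice_146,2,female,healthy,,157,pathological,0.671,healthy,0.206,healthy,2.481,pathological,
voice_147,1,male,pathological,,215,pathological,1.306,pathological,3.903,pathological,6.217,pathological,
voice_147,2,male,pathological,,222,pathological,1.288,pathological,2.0585,pathological,5.836,pathological,
voice_167,1,female,pathological,,325,pathological,1.075,pathological,3.861,pathological,0.783,pathological,
voice_167,2,female,pathological,,305,pathological,1.065,pathological,1.037,pathological,2.518,pathological,
voice_169,1,male,pathological,,647,pathological,1.306,pathological,2.453,pathological,13.033,pathological,
voice_169,2,male,pathological,,603,pathological,1.306,pathological,1.363,pathological,13.625,pathological,
voice_179,1,female,healthy,,239,healthy,1.306,pathological,7.959,pathological,13.551,pathological,
voice_179,2,female,healthy,,237,healthy,1.306,pathological,1.844,pathological,17.641,pathological,
voice_182,1,female,healthy,,215,healthy,1.306,pathological,2.779,pathological,22.578,healthy,
voice_182,2,female,healthy,,216,healthy,1.306,pathological,6.293,pathological,25.158,healthy,
voice_188,1,female,pathological,corrupted_coughs,261,pathological,0.901,healthy,0.107,healthy,9.105,pathological,f0
voice_188,2,female,pathological,corrupted_coughs,250,healthy,1.247,pathological,1.272,pathological,11.219,pathological,
voice_193,1,male,pathological,,377,pathological,1.061,pathological,0.367,pathological,15.522,pathological,
voice_193,2,male,pathological,,356,pathological,1.321,pathological,2.803,pathological,14.917,pathological,
voice_194,1,female,pathological,,524,pathological,1.306,pathological,3.466,pathological,0.682,pathological,
voice_194,2,female,pathological,,505,pathological,1.279,pathological,2.549,pathological,0.821,pathological,
voice_197,1,female,healthy,,225,healthy,1.305,pathological,2.153,pathological,24.895,healthy,
voice_197,2,female,healthy,,212,healthy,1.259,pathological,1.842,pathological,21.939,healthy,
voice_203,1,female,pathological,,135,pathological,1.154,pathological,1.929,pathological,11.343,pathological,
voice_203,2,female,pathological,,119,pathological,1.046,pathological,0.016,healthy,14.344,pathological,
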