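category,gender,n
healthy,female,37
healthy,male,21
hyperkinetic_dysphonia,female,47
hyperkinetic_dysphonia,male,23
hypokinetic_dysphonia,female,32
hypokinetic_dysphonia,male,9
reflux_laryngitis,female,19
reflux_laryngitis,male,20
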