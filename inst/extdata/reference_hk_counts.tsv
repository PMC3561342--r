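quantity	value
normal_HK	8831
cancer_HK	7084
shared	6237
total_loci	18874
shared_constant	1518
shared_moderate_variable	3812
shared_variable	907
shared_constant_alt	2417
shared_moderate_variable_alt	2464
shared_variable_alt	1356
cancer_associated_constant	105
cancer_associated_moderate_variable	361
cancer_associated_variable	381
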