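fdr_threshold: 0.1
p_threshold: 0.1
shared_min_groups: 10
shared_fc_threshold: 1.3219281
specific_min_groups: 5
high_fc_threshold: 3.0
pseudocount: 1.0
fdr_on: anova
p_on: bonferroni
var_equal: true
seed: 1
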