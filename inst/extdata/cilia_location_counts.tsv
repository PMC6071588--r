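location	n_yes	n_potential
axoneme	7	0
basal_body_centriole	2	0
base_of_cilia	6	0
other_unknown	2	7
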