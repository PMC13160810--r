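alternative,reported_s_plus,reported_s_minus,reported_closeness,reported_rank
design_scheme,0.259,3.211,0.894,1
evaluation_sample,1.682,0.549,0.167,2
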