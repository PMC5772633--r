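compound,receptor_form,ic50_nM,l_nM,kd_nM
cmpd1,wt,6.8,1,1
cmpd1,I183F,95.2,1,1
cmpd1,V189A,54.4,1,1
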