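patient_id,lesion_id,adc_baseline,adc_change_w1,adc_change_w2,adc_change_w6
1,1,1.436,0.293,0.348,0.298
2,1,1.348,-0.095,-0.073,0.045
3,1,1.007,0.789,0.111,0.328
4,1,1.341,0.158,-0.223,0.249
5,1,1.454,-0.006,0.177,0.022
6,1,1.702,-0.034,0.046,0.529
7,1,1.215,-0.316,-0.043,-0.255
7,2,1.268,-0.273,-0.353,-0.136
8,1,0.998,0.018,0.046,0.074
8,2,1.286,-0.251,0.010,0.052
9,1,1.823,-0.331,-0.173,-0.411
9,2,1.906,-0.275,0.032,0.353
9,3,1.940,-0.105,-0.71,-0.755
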