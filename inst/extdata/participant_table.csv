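participant,age,age_at_nde,shss,greyson_total
P1,60,21,6,18
P2,44,12,9,7
P3,66,57,8,15
P4,71,8,9,15
P5,48,18,4,12
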