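morph_low,morph_high,label
9670,9670,CLL/SLL
9823,9823,CLL/SLL
9680,9680,DLBCL
9684,9684,DLBCL
9690,9691,FL
9695,9695,FL
9698,9698,FL
9673,9673,MCL
9689,9689,MZL
9699,9699,MZL
9702,9702,PTCL
9705,9705,PTCL
9708,9708,PTCL
9714,9714,PTCL
9716,9719,PTCL
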