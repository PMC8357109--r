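cells,delta_p_pa,y_plus
2000000,104,4.65602
3500000,39,3.36864
7000000,25,3.93312
10300000,22,3.88864
16500000,20,3.94373
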