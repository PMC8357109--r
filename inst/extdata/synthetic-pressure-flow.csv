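naris,phase,timepoint,delta_p_pa,flow_cm3_s
right,inhale,pre,50,110
right,inhale,pre,100,200
right,inhale,pre,150,270
left,inhale,pre,50,90
left,inhale,pre,100,165
left,inhale,pre,150,225
right,inhale,post,50,160
right,inhale,post,100,290
right,inhale,post,150,395
left,inhale,post,50,140
left,inhale,post,100,255
left,inhale,post,150,350
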