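litter_id,group,pnd,pre_weight_g,post_weight_g,duration_h,litter_size
NP1,NP,11,176.86,179.17,1,8
NP1,NP,12,176.74,178.53,1,8
NP1,NP,13,175.96,176.94,1,8
NP1,NP,14,175.35,179.61,1,8
LP1,LP,11,177.17,180.46,1,8
LP1,LP,12,175.74,177.21,1,8
LP1,LP,13,175.63,176.9,1,8
LP1,LP,14,175.59,176.41,1,8
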