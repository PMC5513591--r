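dam_id,group,d2o_mass_g,dam_body_mass_g,purity,litter_mass_g,litter_size
NP1,NP,1.77342,354.683,0.999,175.488,8
LP1,LP,1.39102,278.203,0.999,176.407,8
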