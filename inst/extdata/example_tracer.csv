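dam_id,group,compartment,time_h,conc,units
NP1,NP,dam_plasma,3,0.00608351,gpg
NP1,NP,dam_plasma,24,0.00360381,gpg
NP1,NP,dam_plasma,48,0.00191716,gpg
NP1,NP,dam_plasma,72,0.00109738,gpg
NP1,NP,litter_urine,24,0.0022469,gpg
NP1,NP,litter_urine,48,0.00268667,gpg
NP1,NP,litter_urine,72,0.00232515,gpg
NP1,NP,litter_urine,96,0.00182213,gpg
LP1,LP,dam_plasma,3,0.0063883,gpg
LP1,LP,dam_plasma,24,0.00420327,gpg
LP1,LP,dam_plasma,48,0.00259229,gpg
LP1,LP,dam_plasma,72,0.00161628,gpg
LP1,LP,litter_urine,24,0.00129357,gpg
LP1,LP,litter_urine,48,0.00163049,gpg
LP1,LP,litter_urine,72,0.00152199,gpg
LP1,LP,litter_urine,96,0.00126502,gpg
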