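species,treatment,temperature_C,replicate,seeds_sown,n_germinated,viable_ungerminated,asynchrony,synchrony,germination_fraction
demo,fresh,20,R1,50,4,40,0.811278124459133,0.5,0.08
demo,fresh,20,R2,50,4,44,1,0.333333333333333,0.08
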