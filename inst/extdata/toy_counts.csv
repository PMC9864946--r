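species,treatment,replicate,temperature_C,day,n_germinated,seeds_sown,viable_ungerminated
demo,fresh,R1,20,2,3,50,40
demo,fresh,R1,20,3,1,50,40
demo,fresh,R2,20,2,2,50,44
demo,fresh,R2,20,3,2,50,44
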