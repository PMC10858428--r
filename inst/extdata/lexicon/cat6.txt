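# Category 6: nonasthma medications used to treat AD.
triamcinolone
hydrocortisone
tacrolimus
pimecrolimus
clobetasol
dupilumab
topical steroid
emollient
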