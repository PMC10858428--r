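# Category 2: hay fever allergies.
hay fever
hayfever
allergic rhinitis
seasonal allergies
pollen allergy
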