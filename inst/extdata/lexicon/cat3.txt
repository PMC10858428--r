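# Category 3: atopic (food and related) allergies.
food allergy
food allergies
peanut allergy
egg allergy
milk allergy
shellfish allergy
atopy
atopic allergies
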