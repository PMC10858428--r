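# Category 1: direct mention of atopic dermatitis.
# "AD" as a bare abbreviation is ambiguous (e.g. right ear in otology notes);
# it is disabled by default. Uncomment to enable.
atopic dermatitis
atopic eczema
# ad
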