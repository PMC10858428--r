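# Category 5: dry or itchy skin.
dry skin
itchy
itching
itchiness
pruritus
xerosis
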