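# Category 4: eczema or rashes.
eczema
rash
rashes
flexural dermatitis
flexural involvement
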