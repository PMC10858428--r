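# Category 7: asthma.
asthma
asthmatic
wheezing
reactive airway disease
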