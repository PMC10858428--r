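# Category 8: asthma medications. "hfa" alone is ambiguous (high-functioning
# autism, health facility administrator); it is only matched adjacent to a
# known inhaler brand token.
albuterol
montelukast
budesonide
omalizumab
mepolizumab
benralizumab
flovent hfa
atrovent hfa
xopenex hfa
proair hfa
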