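# trigger<TAB>status<TAB>direction(forward|backward)
no	negated	forward
not	negated	forward
denies	negated	forward
denied	negated	forward
without	negated	forward
never	negated	forward
no evidence of	negated	forward
no history of	negated	forward
negative for	negated	forward
free of	negated	forward
ruled out	negated	backward
resolved	negated	backward
mother	experiencer_other	forward
father	experiencer_other	forward
mom	experiencer_other	forward
dad	experiencer_other	forward
brother	experiencer_other	forward
sister	experiencer_other	forward
grandmother	experiencer_other	forward
grandfather	experiencer_other	forward
aunt	experiencer_other	forward
uncle	experiencer_other	forward
sibling	experiencer_other	forward
family history	experiencer_other	forward
family history of	experiencer_other	forward
if	hypothetical	forward
return if	hypothetical	forward
rule out	hypothetical	forward
possible	hypothetical	forward
possibly	hypothetical	forward
may have	hypothetical	forward
could be	hypothetical	forward
concern for	hypothetical	forward
risk of	hypothetical	forward
monitor for	hypothetical	forward
watch for	hypothetical	forward
suspected	hypothetical	forward
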