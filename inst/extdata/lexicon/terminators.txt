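# Scope terminators: a modifier trigger's scope ends at the first terminator.
but
however
although
except
aside from
;
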