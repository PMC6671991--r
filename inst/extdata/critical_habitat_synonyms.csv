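raw,canonical
no effect,no effect
nlaa,NLAA
not likely to adversely affect,NLAA
no adverse modification,no adverse modification
no destruction or adverse modification,no adverse modification
adverse modification,adverse modification
destruction or adverse modification,adverse modification
no critical habitat,no critical habitat
no ch,no critical habitat
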