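raw,canonical
no effect,no effect
ne,no effect
nlaa,NLAA
not likely to adversely affect,NLAA
"may affect, not likely to adversely affect",NLAA
laa,LAA
likely to adversely affect,LAA
"may affect, likely to adversely affect",LAA
no jeopardy,no jeopardy
nj,no jeopardy
non-jeopardy,no jeopardy
jeopardy,jeopardy
proposed no jeopardy,proposed no jeopardy
proposed jeopardy,proposed jeopardy
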