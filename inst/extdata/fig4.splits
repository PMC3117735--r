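# Two 6-leaf trees at Robinson-Foulds distance 2; their strict consensus
# keeps ab|cdef and abc|def.
a | b c d e f
b | a c d e f
c | a b d e f
d | a b c e f
e | a b c d f
f | a b c d e
a b | c d e f
a b c | d e f
a b c d | e f

a | b c d e f
b | a c d e f
c | a b d e f
d | a b c e f
e | a b c d f
f | a b c d e
a b | c d e f
a b c | d e f
a b c e | d f
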