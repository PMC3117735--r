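# Two 8-leaf caterpillar-like trees on one leafset where a single noisy leaf
# (d) drives the Robinson-Foulds distance to its maximum of 10, while the
# unit-cost edit distance is 6.
a | b c d e f g h
b | a c d e f g h
c | a b d e f g h
d | a b c e f g h
e | a b c d f g h
f | a b c d e g h
g | a b c d e f h
h | a b c d e f g
g h | a b c d e f
f g h | a b c d e
e f g h | a b c d
a e f g h | b c d
a b e f g h | c d

a | b c d e f g h
b | a c d e f g h
c | a b d e f g h
d | a b c e f g h
e | a b c d f g h
f | a b c d e g h
g | a b c d e f h
h | a b c d e f g
f g | a b c d e h
d f g | a b c e h
d f g h | a b c e
d e f g h | a b c
a d e f g h | b c
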