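# Two 9-leaf trees on different leafsets (abcdefghi vs abcdefghj) used for
# frequent-subsplit mining; their strict representative splitset has 12
# members.
a | b c d e f g h i
b | a c d e f g h i
c | a b d e f g h i
d | a b c e f g h i
e | a b c d f g h i
f | a b c d e g h i
g | a b c d e f h i
h | a b c d e f g i
i | a b c d e f g h
c d | a b e f g h i
b c d | a e f g h i
a b c d | e f g h i
h i | a b c d e f g
g h i | a b c d e f
f g h i | a b c d e

a | b c d e f g h j
b | a c d e f g h j
c | a b d e f g h j
d | a b c e f g h j
e | a b c d f g h j
f | a b c d e g h j
g | a b c d e f h j
h | a b c d e f g j
j | a b c d e f g h
b c | a d e f g h j
a b c | d e f g h j
a b c d | e f g h j
h j | a b c d e f g
g h j | a b c d e f
f g h j | a b c d e
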