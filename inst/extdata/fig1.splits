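# Two 5-leaf trees differing by one contraction (T1 refines T2).
# Split-file profile: blank line separates trees; trivial splits included.
a | b c d e
b | a c d e
c | a b d e
d | a b c e
e | a b c d
a b | c d e
a b e | c d

a | b c d e
b | a c d e
c | a b d e
d | a b c e
e | a b c d
a b | c d e
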