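# Pruning example: the 5-leaf input tree and its 4-leaf p-subtree after
# pruning leaf d (one forced contraction: abe|cd degenerates).
a | b c d e
b | a c d e
c | a b d e
d | a b c e
e | a b c d
a b | c d e
a b e | c d

a | b c e
b | a c e
c | a b e
e | a b c
a b | c e
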