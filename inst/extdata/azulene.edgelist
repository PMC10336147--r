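# azulene skeleton: a pentagon and a heptagon sharing one bond
# (the repeating motif of the C5C7 nanotube net)
0 1
1 2
2 3
3 4
4 0
3 5
5 6
6 7
7 8
8 9
9 4
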