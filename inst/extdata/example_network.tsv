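# natind edge list: i j stiffness natural_length layer [creep_rate]
# a 4-mass example: an elastic square frame (P) with plastic diagonals (L)
# pos 0 0.0 0.0
# pos 1 1.0 0.0
# pos 2 1.0 1.0
# pos 3 0.0 1.0
0 1 10 1 P
1 2 10 1 P
2 3 10 1 P
0 3 10 1 P
0 2 1 1.2 L 0.01
1 3 1 1.2 L 0.01
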