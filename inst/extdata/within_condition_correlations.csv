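vowel,hn1_hn2,hn1_hn3,hn2_hn3,n1_n2,n1_n3,n2_n3
bee,0.91,0.91,0.90,0.94,0.97,0.98
bell,0.82,0.81,0.84,0.93,0.95,0.97
book,0.92,0.88,0.85,0.96,0.96,0.98
boot,0.89,0.89,0.91,0.94,0.98,0.94
bow,0.92,0.88,0.89,0.92,0.96,0.92
burn,0.95,0.86,0.89,0.89,0.91,0.95
dawn,0.80,0.90,0.91,0.94,0.92,0.97
den,0.90,0.85,0.92,0.98,0.94,0.95
doll,0.95,0.91,0.92,0.92,0.96,0.95
dune,0.93,0.84,0.90,0.95,0.96,0.97
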