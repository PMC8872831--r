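vowel,mean_within_hn,mean_within_n,mean_across
bee,0.91,0.97,0.90
bell,0.83,0.95,0.74
book,0.88,0.97,0.70
boot,0.90,0.95,0.84
bow,0.90,0.93,0.57
burn,0.90,0.92,0.81
dawn,0.87,0.94,0.71
den,0.89,0.96,0.75
doll,0.93,0.94,0.79
dune,0.89,0.96,0.74
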