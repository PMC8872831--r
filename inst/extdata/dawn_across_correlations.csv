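pair,rho
N1-HN1,0.67
N1-HN2,0.61
N1-HN3,0.65
N2-HN1,0.78
N2-HN2,0.71
N2-HN3,0.72
N3-HN1,0.80
N3-HN2,0.72
N3-HN3,0.74
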