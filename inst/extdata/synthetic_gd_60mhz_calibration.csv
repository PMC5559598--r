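"concentration_mM","R1_per_ms","R2_per_ms"
0.05,0.000435294117647059,0.00060231884057971
0.1,0.000635294117647059,0.00084231884057971
0.2,0.00103529411764706,0.00132231884057971
0.35,0.00163529411764706,0.00204231884057971
0.5,0.00223529411764706,0.00276231884057971
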