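nmol_pnp,a405
0,0.000
1,0.056
2,0.112
4,0.225
6,0.337
8,0.449
10,0.561
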