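level	mean_rls
0	36.1
0.34	29.8
1	23.2
2.1	19.5
5.2	17.1
9.4	16.8
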