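position COMBINED_rate(cM/Mb) Genetic_Map(cM)
0 1.0 0.0
1000000 2.0 1.0
3000000 0.5 5.0
5000000 0.0 6.0
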