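ms 8 1 -t 5.0
1234 5678 9012

//
segsites: 6
positions: 0.05 0.20 0.35 0.50 0.75 0.90
010010
110000
001011
010010
100101
001100
111000
000110
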