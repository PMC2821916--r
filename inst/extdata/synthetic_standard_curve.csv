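amount_ng,intensity
1000,2012
500,1003
250,508
200,407
150,303
100,208
50,104
25,57
10,24
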