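arm,stage,mean,n
0,1,-0.082,71
1,1,0.413,71
2,1,1.766,71
3,1,1.567,71
0,2,0.049,71
2,2,1.451,71
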