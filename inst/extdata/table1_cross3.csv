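dam,1,2,3,4,5,6,7,8,9,10
1,0,0,2,0,0,0,0,0,0,0
2,0,0,0,0,0,0,0,0,0,0
3,0,0,0,0,0,0,0,0,0,0
4,0,0,0,0,0,0,0,0,0,0
5,0,0,0,0,0,0,0,0,0,0
6,0,0,0,0,0,0,0,0,0,0
7,0,0,0,0,0,0,0,0,0,0
8,0,429,130,0,0,1,0,0,1,3
9,0,0,0,0,0,0,0,0,0,0
10,0,0,0,0,0,0,0,0,0,0
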