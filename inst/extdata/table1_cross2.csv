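dam,1,2,3,4,5,6,7,8,9,10
1,0,0,0,0,0,0,0,0,0,0
2,0,16,0,14,9,29,0,5,3,2
3,0,0,8,0,0,0,0,7,0,3
4,0,8,4,0,3,0,19,1,0,1
5,0,1,3,37,0,2,0,3,0,0
6,0,0,2,10,24,0,0,0,0,0
7,0,6,28,2,5,26,1,0,0,0
8,0,0,0,5,0,0,22,0,3,112
9,0,6,0,10,0,0,0,0,0,0
10,0,38,4,16,0,1,1,54,0,0
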