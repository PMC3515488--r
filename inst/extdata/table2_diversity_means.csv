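cross,set,N,A,Ho,He,f
1,parent,20,6.0,0.71,0.68,-0.05
1,offspring,784,5.8,0.73,0.66,-0.10
2,parent,20,7.2,0.75,0.76,0.01
2,offspring,554,7.0,0.77,0.72,-0.07
3,parent,20,6.9,0.74,0.73,-0.02
3,offspring,566,5.2,0.66,0.58,-0.15
4,parent,20,6.7,0.77,0.74,-0.04
4,offspring,563,4.4,0.64,0.55,-0.18
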