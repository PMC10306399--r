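mixture,level,total_uM,each_uM_printed
mixture1,1,0.4,0.2
mixture1,2,2,1
mixture1,3,4,2
mixture1,4,20,10
mixture1,5,40,20
mixture1,6,100,50
mixture2,1,0.18,0.02
mixture2,2,1.8,0.2
mixture2,3,9,1
mixture2,4,18,2
mixture2,5,45,5
mixture2,6,100,11.1
mixture3,1,0.22,0.02
mixture3,2,2.2,0.2
mixture3,3,11,1
mixture3,4,22,2
mixture3,5,55,5
mixture3,6,100,9
mixture4,1,0.22,0.02
mixture4,2,2.2,0.2
mixture4,3,11,1
mixture4,4,22,2
mixture4,5,55,5
mixture4,6,100,9
mixture5,1,0.24,0.02
mixture5,2,2.4,0.2
mixture5,3,12,1
mixture5,4,24,2
mixture5,5,60,5
mixture5,6,100,8.3
mixture6,1,0.6,0.2
mixture6,2,3,1
mixture6,3,6,2
mixture6,4,30,10
mixture6,5,60,20
mixture6,6,100,33.3
mixture7,1,0.4,0.2
mixture7,2,2,1
mixture7,3,4,2
mixture7,4,20,10
mixture7,5,40,20
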