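mixture,component,molarity_uM
mixture1,PFOA,50
mixture1,PFOS,50
mixture2,PFBA,11.1111111111111
mixture2,PFPeA,11.1111111111111
mixture2,PFHxA,11.1111111111111
mixture2,PFHpA,11.1111111111111
mixture2,PFOA,11.1111111111111
mixture2,PFNA,11.1111111111111
mixture2,PFBS,11.1111111111111
mixture2,PFHxS,11.1111111111111
mixture2,PFOS,11.1111111111111
mixture3,PFBA,9.09090909090909
mixture3,PFPeA,9.09090909090909
mixture3,PFHxA,9.09090909090909
mixture3,PFHpA,9.09090909090909
mixture3,PFOA,9.09090909090909
mixture3,PFNA,9.09090909090909
mixture3,PFBS,9.09090909090909
mixture3,PFHxS,9.09090909090909
mixture3,PFOS,9.09090909090909
mixture3,FtS_6_2,9.09090909090909
mixture3,FtS_8_2,9.09090909090909
mixture4,PFBA,9.09090909090909
mixture4,PFPeA,9.09090909090909
mixture4,PFHxA,9.09090909090909
mixture4,PFHpA,9.09090909090909
mixture4,PFOA,9.09090909090909
mixture4,PFNA,9.09090909090909
mixture4,PFDA,9.09090909090909
mixture4,PFUnA,9.09090909090909
mixture4,PFBS,9.09090909090909
mixture4,PFHxS,9.09090909090909
mixture4,PFOS,9.09090909090909
mixture5,PFBA,8.33333333333333
mixture5,PFPeA,8.33333333333333
mixture5,PFHxA,8.33333333333333
mixture5,PFHpA,8.33333333333333
mixture5,PFOA,8.33333333333333
mixture5,PFNA,8.33333333333333
mixture5,PFDA,8.33333333333333
mixture5,PFUnA,8.33333333333333
mixture5,PFBS,8.33333333333333
mixture5,PFHxS,8.33333333333333
mixture5,PFOS,8.33333333333333
mixture5,PFOSA,8.33333333333333
mixture6,PFOA,33.3333333333333
mixture6,PFNA,33.3333333333333
mixture6,PFOS,33.3333333333333
mixture7,FtS_6_2,20
mixture7,FtS_8_2,20
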