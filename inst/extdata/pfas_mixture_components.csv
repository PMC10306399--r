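mixture,component
mixture1,PFOA
mixture1,PFOS
mixture2,PFBA
mixture2,PFPeA
mixture2,PFHxA
mixture2,PFHpA
mixture2,PFOA
mixture2,PFNA
mixture2,PFBS
mixture2,PFHxS
mixture2,PFOS
mixture3,PFBA
mixture3,PFPeA
mixture3,PFHxA
mixture3,PFHpA
mixture3,PFOA
mixture3,PFNA
mixture3,PFBS
mixture3,PFHxS
mixture3,PFOS
mixture3,FtS_6_2
mixture3,FtS_8_2
mixture4,PFBA
mixture4,PFPeA
mixture4,PFHxA
mixture4,PFHpA
mixture4,PFOA
mixture4,PFNA
mixture4,PFDA
mixture4,PFUnA
mixture4,PFBS
mixture4,PFHxS
mixture4,PFOS
mixture5,PFBA
mixture5,PFPeA
mixture5,PFHxA
mixture5,PFHpA
mixture5,PFOA
mixture5,PFNA
mixture5,PFDA
mixture5,PFUnA
mixture5,PFBS
mixture5,PFHxS
mixture5,PFOS
mixture5,PFOSA
mixture6,PFOA
mixture6,PFNA
mixture6,PFOS
mixture7,FtS_6_2
mixture7,FtS_8_2
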