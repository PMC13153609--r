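gene,mw_kda
CCT5,60
CPNE1,59
FUS,70
HSPA4,94
ENO1,47
EIF5A,17
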