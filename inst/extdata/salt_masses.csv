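salt,molar_mass
LiCl,42.394
LiBr,86.844
LiI,133.844
NaCl,58.443
NaBr,102.894
NaI,149.894
KCl,74.548
KBr,119.002
KI,166.002
RbCl,120.918
RbBr,165.372
RbI,212.372
CsCl,168.355
CsBr,212.809
CsI,259.809
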