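salt,A,B,alpha1,alpha2
LiCl,1.7964,1.4374,0.23869,2.4656e-2
LiBr,1.7964,1.6147,0.25376,4.4561e-2
LiI,1.7964,3.0262,0.19784,8.5002e-2
NaCl,1.7964,1.5111,9.78620e-2,2.0657e-2
NaBr,1.7964,1.3145,0.17100,2.2058e-2
NaI,1.7964,2.0662,0.14694,4.3132e-2
KCl,1.7964,1.0587,0.17598,-3.7167e-3
KBr,1.7964,0.98099,0.21795,-4.3250e-4
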