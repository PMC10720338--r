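salt,sigma_A,eps_K,chi,sigma_opt_A,eps_opt_K
LiCl,3.1787,17.524,0.75,3.4895,10.014
LiBr,3.1859,28.283,0.90,3.5456,14.886
LiI,3.3498,33.141,1.06,3.7786,16.088
NaCl,3.5511,22.303,-0.32,3.3300,32.798
NaBr,3.5582,35.996,-0.41,3.2587,61.010
NaI,3.7222,42.178,-0.55,3.2584,93.729
KCl,3.8754,28.728,0.25,4.0223,22.982
KBr,3.8825,46.366,-0.30,3.6585,66.237
KI,4.0465,54.329,0.20,4.1713,45.274
RbCl,3.9814,35.765,0.50,4.2598,23.843
RbBr,3.9886,57.723,0.43,4.2336,40.366
RbI,4.1525,67.637,0.35,4.3655,50.102
CsCl,4.1409,34.129,0.34,4.3479,25.469
CsBr,4.1480,55.083,0.22,4.2878,45.150
CsI,4.3119,64.544,0.00,4.3119,64.544
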