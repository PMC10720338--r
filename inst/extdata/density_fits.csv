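salt,rho_w0,theta1_mu,theta32_mu,theta2_mu,theta1_P,theta32_P,theta2_P
LiCl,0.99702,1.2346e-2,-2.3566e-3,2.7688e-4,1.0546e-2,-2.0884e-3,-7.0290e-5
LiBr,0.99712,3.9357e-2,1.0385e-3,-1.6204e-3,3.7330e-2,1.6557e-3,-2.1963e-3
LiI,0.99713,6.3490e-2,-7.1690e-4,-2.2102e-3,6.1383e-2,-1.2910e-5,-2.8867e-3
NaCl,0.99700,6.2948e-2,-7.1889e-3,-4.1790e-5,6.0936e-2,-6.5261e-3,-5.7990e-4
NaBr,0.99695,9.9941e-2,-5.4726e-3,-1.0888e-3,9.7856e-2,-4.5989e-3,-1.8555e-3
NaI,0.99700,0.13606,-1.4879e-3,-3.1384e-3,0.13343,2.3562e-4,-4.3985e-3
KCl,0.99713,4.9510e-2,-5.3635e-3,-6.2850e-4,4.7929e-2,-5.4872e-3,-7.0140e-4
KBr,0.99680,9.9842e-2,-5.3608e-3,-1.8468e-3,9.8248e-2,-5.3708e-3,-2.1235e-3
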