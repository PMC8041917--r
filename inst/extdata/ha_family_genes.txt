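Adamts13
Ap2a2
Ccnd3
Cd44
Cemip
Cltc
Fgf2
Gusb
Habp2
Habp4
Has1
Has2
Has3
Hexa
Hexb
Hmmr
Hyal1
Hyal2
Hyal3
Il1b
Il15
Itih1
Itih2
Itih3
Itih4
Itih5
Lyve1
Nfkb1
Pdgfb
Ptger4
Ptx3
Shroom4
Stab2
Smpd3
Tgfb1
Tlr4
Tmem2
Tnfaip6
Vcan
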