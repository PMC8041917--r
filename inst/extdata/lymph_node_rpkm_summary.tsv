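gene_id	nmr_mean	nmr_sd	mouse_mean	mouse_sd
Has1	2.09	0.64	0.022	0.01
Has2	0.76	0.28	1.58	0.32
Has3	1.06	1.21	0.61	0.10
Hyal1	0.64	0.20	1.86	0.49
Hyal2	7.49	2.94	13.41	3.18
Hyal3	24.96	15.93	0.19	0.02
Tmem2	14.254	4.43	11.510	3.28
Tnfaip6	36.86	6.97	0.64	0.10
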