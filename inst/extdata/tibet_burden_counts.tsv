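gene	case_carriers	case_total	control_carriers	control_total	p_published
NPIPA3	13	46	2	51	0.000920854
MUC12	39	46	30	51	0.004284524
AGAP7	6	46	0	51	0.009478932
NPIPB5	8	46	1	51	0.01008246
SPATA31A7	11	46	3	51	0.011902438
POTEI	44	46	40	51	0.012244578
FCGBP	19	46	10	51	0.017244393
C10orf120	7	46	1	51	0.020693933
ARHGEF11	5	46	0	51	0.021269799
C10orf112	5	46	0	51	0.021269799
ZNF544	9	46	3	51	0.0404848
GOLGA6L3	6	46	1	51	0.041353144
SSH1	6	46	1	51	0.041353144
TPSB2	6	46	1	51	0.041353144
WASH2P	26	46	19	51	0.044718187
ANKRD30A	4	46	0	51	0.047097413
C11orf80	4	46	0	51	0.047097413
CASP5	4	46	0	51	0.047097413
GPRASP2	4	46	0	51	0.047097413
LAMA1	4	46	0	51	0.047097413
MAP2	4	46	0	51	0.047097413
NCR2	4	46	0	51	0.047097413
SELPLG	4	46	0	51	0.047097413
SFN	4	46	0	51	0.047097413
SOGA2	4	46	0	51	0.047097413
SOX18	4	46	0	51	0.047097413
SYCP2	4	46	0	51	0.047097413
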